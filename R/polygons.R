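#' Construct a polygon region
#'
#' A region is a list of polygon parts; each part is a list of closed
#' lon/lat rings (first ring outer, further rings holes, even-odd rule).
#' Rings are closed automatically if the last vertex differs from the
#' first. An optional attribute table carries one row per part (e.g.
#' protected-area name or IUCN category).
#'
#' @param parts List of parts; each part either a two-column matrix (single
#'   ring) or a list of two-column matrices (rings).
#' @param attributes Optional data frame, one row per part.
#' @return An object of class `niche_region`.
#' @export
region_polygons <- function(parts, attributes = NULL) {
  if (inherits(parts, "niche_region")) return(parts)
  if (is.matrix(parts)) parts <- list(parts)
  parts <- lapply(parts, function(p) {
    rings <- if (is.matrix(p)) list(p) else p
    lapply(rings, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2L, nrow(r) >= 3L)
      if (any(r[, 1] < -180 | r[, 1] > 180 | r[, 2] < -90 | r[, 2] > 90)) {
        stop("ring coordinates outside [-180,180] x [-90,90]")
      }
      if (any(r[1L, ] != r[nrow(r), ])) r <- rbind(r, r[1L, ])
      unname(r)
    })
  })
  if (!is.null(attributes)) {
    attributes <- as.data.frame(attributes)
    stopifnot(nrow(attributes) == length(parts))
  }
  structure(list(parts = parts, attributes = attributes),
            class = "niche_region")
}

#' @export
print.niche_region <- function(x, ...) {
  cat(sprintf("<niche_region> %d polygon part(s)\n", length(x$parts)))
  invisible(x)
}

#' Test whether points fall inside a region
#'
#' Even-odd (ray casting) rule within each part, union across parts.
#'
#' @param region A `niche_region`.
#' @param lon,lat Point coordinates in degrees.
#' @return Logical vector.
#' @export
region_contains <- function(region, lon, lat) {
  region <- region_polygons(region)
  pts <- cbind(lon, lat)
  inside <- rep(FALSE, nrow(pts))
  for (part in region$parts) {
    bnd <- do.call(rbind, lapply(part, function(r) rbind(r, c(NA, NA))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

#' Axis-aligned rectangle region
#'
#' Convenience constructor used by the synthetic generators and tests.
#'
#' @param lon_min,lon_max,lat_min,lat_max Rectangle bounds in degrees.
#' @return A `niche_region` with one rectangular part.
#' @export
rect_region <- function(lon_min, lon_max, lat_min, lat_max) {
  region_polygons(cbind(c(lon_min, lon_max, lon_max, lon_min, lon_min),
                        c(lat_min, lat_min, lat_max, lat_max, lat_min)))
}

#' Read region polygons from GeoJSON
#'
#' Accepts FeatureCollection, Feature, or bare Polygon/MultiPolygon
#' geometries; feature properties populate the attribute table.
#'
#' @param path Path to a GeoJSON file.
#' @return A `niche_region`.
#' @export
read_region_geojson <- function(path) {
  if (!file.exists(path)) stop("cannot read polygons: no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(doc$type %||% "",
                  FeatureCollection = doc$features,
                  Feature = list(doc),
                  Polygon = ,
                  MultiPolygon = list(list(geometry = doc, properties = NULL)),
                  stop("unsupported GeoJSON type: ", doc$type))
  parts <- list(); attrs <- list()
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  for (f in feats) {
    g <- f$geometry
    polys <- switch(g$type,
                    Polygon = list(g$coordinates),
                    MultiPolygon = g$coordinates,
                    stop("unsupported geometry type: ", g$type))
    for (poly in polys) {
      parts[[length(parts) + 1L]] <- lapply(poly, ring_mat)
      attrs[[length(attrs) + 1L]] <- f$properties
    }
  }
  at <- NULL
  if (any(lengths(attrs) > 0)) {
    keys <- unique(unlist(lapply(attrs, names)))
    at <- as.data.frame(lapply(setNames(keys, keys), function(k) {
      vapply(attrs, function(a) {
        v <- a[[k]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, "")
    }), stringsAsFactors = FALSE)
  }
  region_polygons(parts, attributes = at)
}

#' Write region polygons as GeoJSON
#'
#' @param region A `niche_region`.
#' @param path Output path.
#' @export
write_region_geojson <- function(region, path) {
  region <- region_polygons(region)
  feats <- lapply(seq_along(region$parts), function(i) {
    rings <- lapply(region$parts[[i]], function(r) {
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    })
    props <- if (!is.null(region$attributes)) {
      as.list(region$attributes[i, , drop = FALSE])
    } else NULL
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
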