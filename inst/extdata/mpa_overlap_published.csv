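scenario,period,total_km2,outside_km2,pct_outside,inside_km2,pct_inside,change_inside_km2,change_inside_pct
Current,current,322114,245736,76.3,76379,23.7,NA,NA
SSP1-1.9,2050,319415,243525,75.6,75903,23.6,-476,-0.6
SSP1-2.6,2050,300242,230739,71.6,69509,21.6,-6870,-9.0
SSP2-4.5,2050,280954,220206,68.4,60758,18.9,-15621,-20.5
SSP3-7.0,2050,281461,221937,68.9,59525,18.5,-16854,-22.1
SSP4-6.0,2050,289283,225796,70.1,63492,19.7,-12887,-16.9
SSP5-8.5,2050,257018,207032,64.3,49991,15.5,-26388,-34.5
SSP1-1.9,2100,327945,247956,77.0,79992,24.8,3613,4.7
SSP1-2.6,2100,272900,215828,67.0,57078,17.7,-19301,-25.3
SSP2-4.5,2100,246481,212578,66.0,33921,10.5,-42458,-55.6
SSP3-7.0,2100,166682,152297,47.3,14379,4.5,-62000,-81.2
SSP4-6.0,2100,242219,215741,67.0,26490,8.2,-49889,-65.3
SSP5-8.5,2100,90178,82275,25.5,7904,2.5,-68475,-89.7
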