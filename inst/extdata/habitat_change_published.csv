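scenario,period,total_km2,maintained_km2,pct_maintained,gained_km2,pct_gained,lost_km2,pct_lost,total_change_pct
SSP1-1.9,2050,319415,294540,91.4,24880,7.7,27565,8.6,-0.8
SSP1-2.6,2050,300242,262589,81.5,37664,11.7,59528,18.5,-6.8
SSP2-4.5,2050,280954,234545,72.8,46419,14.4,87574,27.2,-12.8
SSP3-7.0,2050,281461,228057,70.8,53413,16.6,94068,29.2,-12.6
SSP4-6.0,2050,289283,243277,75.5,46017,14.3,78844,24.5,-10.2
SSP5-8.5,2050,257018,201000,62.4,56027,17.4,121118,37.6,-20.2
SSP1-1.9,2100,327945,301943,93.7,26003,8.1,20174,6.3,1.8
SSP1-2.6,2100,272900,217734,67.6,55177,17.1,104388,32.4,-15.3
SSP2-4.5,2100,246481,128565,39.9,117926,36.6,193550,60.1,-23.5
SSP3-7.0,2100,166682,73406,22.8,93276,29.0,248714,77.2,-48.3
SSP4-6.0,2100,242219,100040,31.1,142187,44.1,222077,68.9,-24.8
SSP5-8.5,2100,90178,45990,14.3,44188,13.7,276123,85.7,-72.0
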