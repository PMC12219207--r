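drug,BP,MR,P,MV,E,C,MW
Bromfenac,458.857,78.630,30.728,221.581,83.021,387.944,293.877
CIS-UCA,273.089,39.986,15.441,123.535,59.369,88.655,146.125
Dexamethasone,496.345,104.903,41.446,315.533,95.335,796.940,394.091
Diclofenac,449.288,75.319,29.371,210.235,80.801,341.385,278.808
Cyclosporine,228.858,24.979,9.743,82.800,NA,47.487,95.300
Doxycycline,704.468,109.816,43.040,267.148,115.549,938.447,438.223
Estradiol,527.846,72.056,29.289,202.802,79.213,462.169,271.892
Fluorometholone,511.098,96.131,38.017,276.292,100.934,854.167,390.283
Flurbiprofen,439.629,69.541,27.020,188.198,79.363,328.649,259.511
Hydroxychloroquine,522.831,92.897,35.868,247.125,89.203,360.771,331.784
Ketorolac,398.019,73.397,28.738,199.506,79.488,380.022,254.984
Lifitegrast,NA,153.141,60.722,413.868,123.984,1101.611,615.603
Methylprednisolone,516.872,101.122,39.628,291.208,98.834,753.604,371.964
Minocycline,706.548,116.747,46.069,301.952,115.546,NA,NA
Nepafenac,455.579,74.137,28.429,191.480,83.839,347.325,274.264
Pranoprofen,500.720,71.859,NA,194.351,79.836,369.867,268.006
Rebamipide,591.027,103.883,40.950,289.044,95.722,531.537,384.118
Rimexolone,502.036,99.806,40.421,310.120,91.066,740.852,371.263
Rivoglitazone,675.424,109.789,43.685,298.016,98.225,568.658,401.484
Tacrolimus,879.850,213.494,84.718,670.553,144.440,1483.093,804.678
Tetracycline,671.393,110.129,43.797,295.427,108.671,882.825,433.377
Piperidine,395.023,85.339,33.877,253.326,68.560,294.895,284.116
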