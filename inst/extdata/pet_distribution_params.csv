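accident_type,severity,mean,sd,published_cold_pct,published_hot_pct,published_outside_pct
electric shock,fatal,23.01,13.60,35.83,49.82,85.65
slip,fatal,16.20,13.92,54.82,31.40,86.22
fall,fatal,16.45,13.71,54.49,31.52,86.01
traffic accident,fatal,13.97,15.05,60.71,27.06,87.77
be hit,fatal,16.40,13.85,54.73,31.10,85.83
collision,fatal,15.32,13.52,57.20,28.84,86.04
get jammed,fatal,15.34,14.49,57.86,29.85,87.71
leak or contact of chemicals,fatal,12.26,15.49,63.73,25.18,88.91
fire,fatal,14.16,15.35,60.54,27.12,87.66
bumped,fatal,15.74,14.16,55.63,31.30,86.93
drowned,fatal,14.94,13.18,59.00,27.30,86.30
explosion,fatal,12.67,15.60,63.92,24.97,88.89
hypoxia,fatal,21.69,13.99,39.52,46.11,85.63
violence,fatal,13.26,7.18,74.58,8.73,83.31
contact of abnormal temperature,fatal,24.98,17.96,35.05,53.75,88.80
cut,fatal,22.02,11.67,36.30,46.66,82.96
animal injury,fatal,29.15,5.57,2.54,86.23,88.77
fall beneath,fatal,17.08,13.26,52.89,32.48,85.37
electric shock,injury,23.01,13.60,49.92,35.16,85.08
slip,injury,16.20,13.92,57.57,29.03,86.60
fall,injury,16.45,13.71,55.63,29.97,85.60
traffic accident,injury,13.97,15.05,66.58,21.69,88.27
be hit,injury,16.40,13.85,53.12,32.60,85.72
collision,injury,15.32,13.52,57.62,28.21,85.83
get jammed,injury,15.34,14.49,56.49,29.11,85.60
leak or contact of chemicals,injury,12.26,15.49,50.99,34.79,85.78
fire,injury,14.16,15.35,66.94,22.01,88.95
bumped,injury,15.74,14.16,52.51,32.36,84.87
drowned,injury,14.94,13.18,46.21,38.24,84.45
explosion,injury,12.67,15.60,66.32,22.14,88.46
hypoxia,injury,21.69,13.99,56.75,28.57,85.32
violence,injury,13.26,7.18,60.12,24.82,84.94
contact of abnormal temperature,injury,24.98,17.96,60.59,27.79,88.38
cut,injury,22.02,11.67,51.92,33.50,85.42
animal injury,injury,29.15,5.57,24.90,58.79,83.69
fall beneath,injury,17.08,13.26,53.45,32.22,85.67
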