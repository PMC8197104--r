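accident_type,fatal_total,injury_total
electric shock,215,1601
slip,119,34129
fall,2804,71078
traffic accident,392,1968
be hit,350,28576
collision,391,3742
get jammed,193,18921
leak or contact of chemicals,48,491
fire,70,813
bumped,292,19849
drowned,97,25
explosion,91,935
hypoxia,43,33
violence,7,127
contact of abnormal temperature,18,975
cut,13,19071
animal injury,13,94
fall beneath,161,5435
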