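strategy,variant,rate,up_n,births_n,induced_n,spontaneous_n,ectopic_n,birth_unadj_median,birth_unadj_min,birth_unadj_max,total_unadj_median,total_unadj_min,total_unadj_max,total_adj_median,total_adj_min,total_adj_max
OC alone,point,0.3,3,1,1,0,0,19090,7767,42245,20682,8715,48569,9885,4323,24677
OC + enzyme inducer,point,2.3,23,11,8,3,0,144903,58955,320660,156986,66151,368662,75031,32814,187312
OC + enzyme inducer,low,1.9,19,9,7,3,0,119942,48799,265422,129943,54756,305155,62106,27162,155045
OC + enzyme inducer,high,2.8,28,14,10,4,0,175966,71593,389398,190638,80332,447690,91115,39849,227465
OC + enzyme neutral,point,1.6,16,8,6,2,0,101155,41155,223847,109589,46179,257357,52378,22907,130760
OC + enzyme neutral,low,1.4,14,7,5,2,0,88599,36047,196062,95986,40447,225412,45876,20064,114529
OC + enzyme neutral,high,1.8,18,9,6,3,0,113686,46254,251577,123165,51900,289238,58866,25745,146958
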