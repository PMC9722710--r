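comparison,delta_up,unadj_median,unadj_min,unadj_max,adj_median,adj_min,adj_max
OC + enzyme inducer vs OC alone,20,136304,46041,399121,65146,22839,202788
OC + enzyme inducer vs OC + enzyme neutral,7,NA,14309,158452,NA,7098,80507
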