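therapy,rss_original,rss_constant,aic_constant,rss_dynamic,aic_dynamic
a,5401,5367.9,42.779,6555.9,51.978
b,26367,5664.4,43.101,8251.0,53.358
c,12332,3240.4,39.750,6474.1,51.903
d,27188,18396.0,50.169,14853.0,56.885
e,249770,739.9,30.889,2330.5,45.772
f,9094.4,1762.4,36.096,9161.8,53.986
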