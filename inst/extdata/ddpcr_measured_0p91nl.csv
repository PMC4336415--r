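level_id,mean,sd,n
f,9,2,8
e,87,10,8
d,846,80,8
c,8851,669,8
b,90951,8105,8
a,908543,58766,8
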