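id,easting,northing,nights_active,total_calls
d01,1000,0,4,172
d02,866.025403784439,500,7,260
d03,500,866.025403784439,7,189
d04,6.12323399573677e-14,1000,7,170
d05,-500,866.025403784439,1,17
d06,-866.025403784439,500,7,132
d07,-1000,1.22464679914735e-13,7,120
d08,-866.025403784439,-500,7,209
d10,-1.83697019872103e-13,-1000,1,51
d11,500,-866.025403784439,7,289
d12,866.025403784438,-500,7,288
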