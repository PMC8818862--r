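# U937-like cell balanced with normal 310 mOsm medium; full NC+KC+NKCC set
na: 38
k: 147
cl: 45
v: 12.5
na0: 140
k0: 5.8
cl0: 116
B0: 48.2
pna: 0.0017
pk: 0.0115
pcl: 0.011
beta: 0.039
gamma: 1.5
inc: 7.0e-5
ikc: 8.0e-5
inkcc: 8.0e-9
U: -45.0
dt: 0.01
hp: 100
duration: 240
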