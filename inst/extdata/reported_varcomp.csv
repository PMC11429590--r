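cross,generation,sigma2_p,sigma2_e,sigma2_pg
crossA,BC1P1,536.94,71.93,239.25
crossA,BC1P2,217.78,71.93,26.25
crossA,F2,410.95,71.93,0.00
crossB,BC1P1,390.70,67.07,33.91
crossB,BC1P2,287.71,67.07,73.31
crossB,F2,558.84,67.07,0.00
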