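{"characters":["A","B","C","D","E","0","1","2","3","4","5","6","7","8","9"],"n_bits":4,"indices":[1,2,3,4,5,6,7,8,9,10,11,12,13,14,15],"layout":{"n_bits":4,"spacing":15,"spot_radius":5,"field_side":451,"grid_rows":2,"grid_cols":2},"noise":{"enabled":true,"mean":0.5,"deviation":0.15}}
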