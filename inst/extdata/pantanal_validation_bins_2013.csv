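bin_top_db,bin_bottom_db,n_target,n_unconfirmed
0,-5,0,0
-5,-10,6,0
-10,-15,4,0
-15,-20,21,0
-20,-25,24,0
-25,-30,48,0
-30,-35,76,1
-35,-40,178,9
-40,-45,246,28
-45,-50,201,82
-50,-Inf,94,334
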