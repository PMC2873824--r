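type,a1,a2,a3,k,ref
bond,N,CA,,337.0,1.449
bond,CA,C,,317.0,1.522
bond,C,N,,490.0,1.335
bond,C,O,,570.0,1.229
bond,CA,CB,,310.0,1.526
angle,N,CA,C,63.0,110.1
angle,CA,C,N,70.0,116.6
angle,C,N,CA,50.0,121.9
angle,CA,C,O,80.0,120.4
angle,O,C,N,80.0,122.9
angle,N,CA,CB,80.0,109.7
angle,CB,CA,C,63.0,111.1
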