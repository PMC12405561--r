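site_id,variable,value
S001,mat,-7.51
S002,mat,27.8
S003,mat,8.06
S004,mat,3.64
S005,mat,5.2
S006,mat,2.82
S007,mat,24.74
S008,mat,3.37
S009,mat,14.06
S010,mat,1.73
S011,mat,15.88
S012,mat,0.38
S001,map,240.7
S002,map,1887.1
S003,map,708.2
S004,map,464.1
S005,map,455.8
S006,map,703.9
S007,map,1851.8
S008,map,876.1
S009,map,887.5
S010,map,476.7
S011,map,1577
S012,map,638.5
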