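site_id,year,temperature,precipitation
S001,2010,-6.92,239.4
S002,2010,27.25,2059.5
S003,2010,8.63,690.9
S004,2010,4.14,452.2
S005,2010,4.65,453.8
S006,2010,3.11,679.1
S007,2010,24.79,1982.1
S008,2010,2.86,874.4
S009,2010,13.73,848.1
S010,2010,1.84,448.7
S011,2010,16.58,1465.1
S012,2010,-0.53,662.9
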