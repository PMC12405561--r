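site_id,soil_texture,ph,fertility_class
S001,sand,6.8,unknown
S002,silt,4.1,unknown
S003,sand,7.8,unknown
S004,sand,4,M
S005,clay,6.3,L
S006,sand,5.3,unknown
S007,sand,5.5,H
S008,clay,6.2,M
S009,loam,7.7,L
S010,sand,5.8,unknown
S011,loam,7.5,unknown
S012,clay,7.1,M
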