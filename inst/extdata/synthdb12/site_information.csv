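site_id,latitude,longitude,elevation,biome,management,climate_region,study_type,species_info,fertility
S001,73.566,-177.8041,188,peatland,unmanaged,polar,field_assessment,,unknown
S002,-15.4163,20.2895,1166,forest,managed,tropical,field_assessment,,unknown
S003,44.6571,110.3478,1319,grassland,unmanaged,temperate,field_assessment,,unknown
S004,56.9412,93.3205,451,peatland,managed,cold,field_assessment,,M
S005,56.4078,104.8944,196,forest,unmanaged,cold,field_assessment,,L
S006,58.8832,90.4565,1050,grassland,unmanaged,cold,field_assessment,,unknown
S007,-19.0166,128.4981,949,forest,managed,tropical,field_assessment,,H
S008,62.2893,115.701,775,forest,unmanaged,cold,field_assessment,,M
S009,-44.6198,160.5706,1395,forest,managed,temperate,field_assessment,,L
S010,53.33,135.0811,430,cropland,managed,cold,manipulation_control,,unknown
S011,-36.5789,62.4005,1285,forest,unmanaged,temperate,manipulation_treatment,,unknown
S012,56.1629,-38.2599,681,forest,managed,cold,field_assessment,,M
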