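site_id,years_since_disturbance,years_since_thinning_or_harvest,years_since_fertilization,years_since_planting,years_protected,grazing_intensity,irrigated,annual_burning,crop,fruit_plantation,above_treeline
S001,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S002,,42,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S003,,,,,,none,FALSE,FALSE,FALSE,FALSE,FALSE
S004,,,0,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S005,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S006,,,,,,none,FALSE,FALSE,FALSE,FALSE,FALSE
S007,,46,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S008,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S009,,42,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S010,,,1,,,,TRUE,FALSE,TRUE,FALSE,FALSE
S011,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
S012,,37,,,,,FALSE,FALSE,FALSE,FALSE,FALSE
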