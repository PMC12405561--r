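method_id,name,scope,rf
BG1,Isotope turnover,belowground,0.2
BG2,Minirhizotron or root window (fine roots),belowground,0.3
BG3,Ingrowth core (fine roots),belowground,0.3
BG4,Allometric relations (coarse roots),belowground,0.6
BG5,Carbon budget and mass balance (all roots),belowground,0.6
BG6,"Sequential coring, with sum of increments in live and dead biomass (fine roots)",belowground,0.7
BG7,Sequential biomass coring (fine roots),belowground,0.8
BG8,Fixed proportion of other NPP component (coarse roots),belowground,0.9
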