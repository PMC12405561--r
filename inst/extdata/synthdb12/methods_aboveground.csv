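method_id,name,scope,rf
AG1,Isotope turnover,aboveground,0.1
AG2,Sum of increments in live biomass adjusted for decomposition,aboveground,0.2
AG3,Sum of increments in live biomass,aboveground,0.3
AG4,Peak standing crop,aboveground,0.4
AG5,Maximum minus minimum live biomass,aboveground,0.4
AG6,Allometric/biometric methods,aboveground,0.4
AG7,Fixed proportion of other NPP component,aboveground,0.8
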