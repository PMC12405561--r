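method_id,name,scope,rf
TO1,Radiocarbon,total,0.6
TO2,Peat formation in peatlands,total,0.6
TO3,Process-based model,total,0.6
TO4,"Flux components, incl. eddy covariance measurements",total,1
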