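site_id,level,value
S001,herb_shrub_anpp,151.0740286678885
S001,non_tree_anpp,209.30818204348304
S001,bnpp,88.32442443116221
S001,total_npp_1,297.6326064746453
S001,total_npp_2,297.6326064746453
S002,wood_anpp,755.8380304534396
S002,total_litterfall_anpp,568.1139395038836
S002,tree_anpp,1323.9519699573232
S002,bnpp,805.1634371319583
S002,total_npp_1,2129.1154070892817
S002,total_npp_2,2129.1154070892817
S003,herb_shrub_anpp,682.8387876835852
S003,non_tree_anpp,682.8387876835852
S003,bnpp,477.710274023065
S003,total_npp_1,1160.5490617066503
S003,total_npp_2,1160.5490617066503
S005,wood_anpp,273.2569372703609
S005,bnpp,277.366935660281
S007,wood_anpp,758.7188781739817
S007,total_litterfall_anpp,573.441443934965
S007,tree_anpp,1332.1603221089467
S007,bnpp,908.8177820961548
S007,total_npp_1,2240.9781042051018
S007,total_npp_2,2240.9781042051018
S008,wood_anpp,306.3212726318403
S008,total_litterfall_anpp,247.34171693510538
S008,tree_anpp,553.6629895669457
S008,bnpp,342.13075866779235
S008,total_npp_1,895.7937482347381
S008,total_npp_2,895.7937482347381
S009,wood_anpp,486.5583620440125
S009,total_litterfall_anpp,353.65739870981594
S009,tree_anpp,840.2157607538284
S010,herb_shrub_anpp,501.45943773234626
S010,non_tree_anpp,501.45943773234626
S010,bnpp,290.03566673834456
S010,total_npp_1,791.4951044706909
S010,total_npp_2,791.4951044706909
S011,wood_anpp,624.6701723240999
S011,total_litterfall_anpp,511.60240970732065
S011,tree_anpp,1136.2725820314206
S011,bnpp,709.2630024094916
S011,total_npp_1,1845.5355844409123
S011,total_npp_2,1845.5355844409123
S012,wood_anpp,235.9250335325442
S012,total_litterfall_anpp,179.55566114146865
S012,tree_anpp,415.48069467401285
S012,bnpp,256.78654481454737
S012,total_npp_1,672.2672394885602
S012,total_npp_2,672.2672394885602
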