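type,vel_high,vel_low,depth_deep,depth_shallow,sub_interstitial,sub_sand,sub_mud,sub_gravel,cov_wood,cov_boulder,pc_oxygen,pc_temperature,pc_nutrient,veg_rheo_moss,veg_macrophyte,veg_canopy,veg_overhang,bank_undercut,floodplain_access,habitat_continuity,flow_stability
dam,0,2,2,0.5,0,1,2,0.5,1,0.5,0,0.5,1.5,0,2,0,0.5,0,0.5,0,0.5
weir,0,2,1.5,0.5,0.5,1.5,2,0.5,1,0.5,0.5,0.5,1.5,0,2,0.5,1,0,0.5,0,0.5
sluice,0.5,1.5,1.5,0.5,0.5,1.5,1.5,0.5,1,0.5,0.5,1,1.5,0.5,1.5,1,1,0.5,0.5,0,0.5
culvert,0.5,1.5,1,1,1,1,1,1,0.5,1,1,1,1,1,1,0.5,0.5,0.5,1,0.5,1
ford,1,1,0.5,1.5,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.5,1
ramp,1,1,1,1,1,1,1,1.5,1,1.5,1,1,1,1,1,1,1,1,1,0.5,1
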