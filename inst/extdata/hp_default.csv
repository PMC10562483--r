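guild_id,vel_high,vel_low,depth_deep,depth_shallow,sub_interstitial,sub_sand,sub_mud,sub_gravel,cov_wood,cov_boulder,pc_oxygen,pc_temperature,pc_nutrient,veg_rheo_moss,veg_macrophyte,veg_canopy,veg_overhang,bank_undercut,floodplain_access,habitat_continuity,flow_stability
RH_INT,1,0,0,1,1,0,0,1,0.5,1,1,1,0.5,1,0,1,0.5,0.5,0,1,1
RB_SG,1,0.5,0.5,1,1,1,0,1,0.5,0.5,1,0.5,0.5,0.5,0,0.5,0.5,0.5,0.5,1,1
RW_SG,1,0.5,0.5,1,0.5,1,0,1,0.5,0.5,1,0.5,0.5,0.5,0,0.5,0.5,0,0.5,1,1
RB_DP,1,0.5,0,1,1,0.5,1,0.5,1,0.5,1,1,0.5,0.5,0,1,0.5,0.5,0.5,1,1
WC_INT,1,0.5,1,0.5,0.5,0,0,0.5,0.5,0.5,1,1,0.5,0.5,0,1,0.5,0.5,0,1,1
LB_MT,0,1,0.5,0.5,0,1,1,0,0.5,0,0.5,0,0.5,0,0.5,0,0.5,0.5,1,0.5,0
LW_MT,0,1,1,0.5,0,0.5,1,0,0.5,0,0.5,0,0.5,0,1,0,0.5,0,1,0.5,0
LL_MT,0.5,1,0.5,0.5,0.5,0,0,1,0,0.5,0.5,0.5,0.5,0,0.5,0,0,0.5,0.5,0.5,0.5
LP_MT,0,1,0.5,1,0,0.5,1,0,0.5,0,0.5,0,0.5,0,1,0,1,0.5,1,0.5,0
B_MT,0.5,0.5,0.5,0.5,0.5,1,1,0.5,0.5,0,0.5,0.5,0.5,0,0.5,0,0,0.5,0.5,0.5,0.5
GEN,0,0.5,0.5,0.5,0,0.5,0.5,0,0.5,0,0,0,0.5,0,0.5,0,0.5,0,0.5,0.5,0
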