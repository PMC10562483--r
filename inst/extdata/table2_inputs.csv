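type,n_height,calc_impoundment_km,calc_remaining_km,p,err
dam,28913,22180,8591,0.483,0.157
weir,59099,38195,18000,0.32,0.582
sluice,4155,6686,3553,0.595,0.72
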