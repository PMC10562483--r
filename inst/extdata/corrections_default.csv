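type,p,err
dam,0.483,0.157
weir,0.32,0.582
sluice,0.595,0.72
culvert,0.25,0.61
ford,0.25,0.61
ramp,0.25,0.61
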