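# device-to-analysis axis map for the synthetic example trial
si: "+x"
ml: "+y"
ap: "+z"
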