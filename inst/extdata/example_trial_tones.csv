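# synthetic demonstration tone track (hand-written, not recorded data)
trial_id,t_tone_ms
demo_bim,500
demo_bim,1000
demo_bim,1500
demo_bim,2000
demo_bim,2500
demo_bim,3000
demo_bim,3500
demo_bim,4000
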