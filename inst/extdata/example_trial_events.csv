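# synthetic demonstration trial (hand-written, not recorded data)
trial_id,subject_id,session,condition,hand,finger,t_on_ms,t_off_ms
demo_bim,demo01,1,2HZ_BIM,R,2,500,711
demo_bim,demo01,1,2HZ_BIM,L,2,516,724
demo_bim,demo01,1,2HZ_BIM,R,3,994,1203
demo_bim,demo01,1,2HZ_BIM,L,3,1012,1220
demo_bim,demo01,1,2HZ_BIM,R,4,1489,1701
demo_bim,demo01,1,2HZ_BIM,L,4,1465,1677
demo_bim,demo01,1,2HZ_BIM,R,5,1982,2195
demo_bim,demo01,1,2HZ_BIM,L,5,2003,2214
demo_bim,demo01,1,2HZ_BIM,R,2,2477,2690
demo_bim,demo01,1,2HZ_BIM,L,2,2492,2704
demo_bim,demo01,1,2HZ_BIM,R,3,2969,3180
demo_bim,demo01,1,2HZ_BIM,L,3,2995,3208
demo_bim,demo01,1,2HZ_BIM,R,4,3464,3676
demo_bim,demo01,1,2HZ_BIM,L,4,3449,3660
demo_bim,demo01,1,2HZ_BIM,R,5,3958,4170
demo_bim,demo01,1,2HZ_BIM,L,5,3981,4192
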