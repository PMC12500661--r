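alternative,criterion_id,preference
experimental,kps,82
experimental,ca211,67
experimental,cea,75
experimental,fatigue,66
experimental,gi,56
control,kps,18
control,ca211,33
control,cea,25
control,fatigue,36
control,gi,24
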