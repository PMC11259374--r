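experiment,manual_dap_uGym2,automatic_dap_uGym2
1,290.78,36.09
2,134.27,31.78
3,250.33,68.61
4,180.77,31.78
5,132.61,45.01
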