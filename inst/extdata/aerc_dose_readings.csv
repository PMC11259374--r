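setting_label,air_kerma_mGy,dap_uGym2
full_field,27,526.2
coil_unaware,336,166.34
coil_aware,25,12.14
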