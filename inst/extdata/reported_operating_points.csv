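variant,horizon_h,sensitivity,specificity
boosted_ctwh_mgp,0,0.818,0.828
recurrent_ctwh_mgp,0,0.807,0.816
boosted_mgp_only,0,0.777,0.785
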