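zone,facility_level,n,zone_total
urban,primary,31011,160652
urban,secondary,41736,160652
urban,tertiary,78544,160652
rural,primary,48539,142565
rural,secondary,48308,142565
rural,tertiary,32861,142565
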