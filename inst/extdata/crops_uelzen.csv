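name,share_pct,harvest_doy,maturity_start_doy
Spring barley,9,219,198
Triticale,4,219,198
Winter barley,12,198,177
Winter rye,5,219,198
Winter wheat,14,219,198
Winter rapeseed,4,183,162
Winter rapeseed with organic fertilisation,2,208,187
Silage maize,5,261,240
Potato,22,265,244
Sugar beet,15,290,269
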