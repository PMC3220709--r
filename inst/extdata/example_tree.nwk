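((uxs_at:0.12,uxs_os:0.10)98:0.31,((uge_at:0.08,uge_cr:0.15)91:0.22,uxe_pp:0.29)64:0.11,outgroup:0.55);
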