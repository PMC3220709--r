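>seed1
MGKVLVTGGAGFIGSHLVDRLM-EGYEVIVLDNLS
>seed2
MGKILVTGGAGYIGSHTVDQLL-DGHEVVVLDNLS
>seed3
MGRVLVTGGSGFIGSHLVDKLLAEGHEVIVIDNLS
>seed4
MGKVLITGGAGFIGSHLVERLL-EGNEVVVLDNFS
>seed5
MARVLVTGGAGFIGSALVDELV-KGHEVVVLDNLS
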