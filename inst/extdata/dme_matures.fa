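>dme-miR-14 Drosophila melanogaster miR-14-3p mature sequence
UCAGUCUUUUUCUCUCUCCUA
>dme-miR-2a Drosophila melanogaster miR-2a-3p mature sequence
UAUCACAGCCAGCUUUGAUGAGC
>dme-bantam Drosophila melanogaster bantam-3p mature sequence
UGAGAUCAUUUUGAAAGCUGAUU
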