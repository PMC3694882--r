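>flank58_v1 synthetic canonical plant 5.8S 3'-end motif (ITS3 primer region)
GCATCGATGAAGAACGCAGC
>flank58_v2
GCATCGATGAAGAACGTAGC
>flank58_v3
GCATCGATGAAGAACGCAGC
>flank58_v4
GCATCGATGAAGAACGCAGC
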