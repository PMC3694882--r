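>flank28_v1 synthetic canonical plant 28S 5'-end motif (ITS4 primer region, plus strand)
GCATATCAATAAGCGGAGGA
>flank28_v2
ACATATCAATAAGCGGAGGA
>flank28_v3
GCATATCAATAAGCGGAGGA
>flank28_v4
GCATATCAATAAGCCGAGGA
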