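>bspec_template_synthetic synthetic stand-in embedding the beta-Spectrin ddPCR primer sites at 107 bp spacing
CCACACGTTCTTGAAGTTTATGCTATCATCACGAAAGTTGATGACGACGGACATTTCGAT
TGCGATATGTCATCTCCACCATACGGCGTAGCACCATCTGAGGGTTTAGAAATTGGAGGC
CGCAAGCAACTCCAGTTCCCGACTGTTGTGAGTACGTCAGAAACACAGCCGATCCAAGTT
CGTGGTA
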