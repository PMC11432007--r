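>alpha1_ecd origin=28 uniprot=P14867 range=Gln28-Arg248
QPSLQDELKDNTTVFTRILDRLLDGYDNRLRPGLGERVTEVKTDIFVTSFGPVSDHDMEY
TIDVFFRQSWKDERLKFKGPMTVLRLNNLMASKIWTPDTFFHNGKKSVAHNMTMPNKLLR
ITEDGTLLYTMRLTVRAECPMHLEDFPMDAHACPLKFGSYAYTRAEVVYEWTREPARSVV
VAEDGSRLNQYDLLGQTVDSGIVQSSTGEYVVMTTHFHLKR
>beta2_ecd origin=25 uniprot=P47870 range=Gln25-Gly243
QSVNDPGNMSFVKETVDKLLKGYDIRLRPDFGGPPVDVGMRIDVASIDMVSEVNMDYTLT
MYFQQYWRDKRLAYSGIPLNLTLDNRVADQLWVPDTYFLNDKKSFVHGVTVKNRMIRLHP
DGTVLYGLRITTTAACMMDLRRYPLDEQNCTLEIESYGYTTDDIEFYWRGGDKAVTGVER
IELPQFSIVEHRLVSRNVVFATGAYPRLSLSFRLKRNIG
>gamma2_ecd origin=40 uniprot=P18507 range=Gln40-Gly273
QKSDDDYEDYASNKTWVLTPKVPEGDVTVILNNLLEGYDNKLRPDIGVKPTLIHTDMYVN
SIGPVNAINMEYTIDIFFAQTWYDRRLKFNSTIKVLRLNSNMVGKIWIPDTFFRNSKKAD
AHWITTPNRMLRIWNDGRVLYTLRLTIDAECQLQLHNFPMDEHSCPLEFSSYGYPREEIV
YQWKRSSVEVGDTRSWRLYQFSFVGLRNTTEVVKTTSGDYVVMSVYFDLSRRMG
>alpha1_ecd_tm origin=28 uniprot=P14867 range=Gln28-Leu296
QPSLQDELKDNTTVFTRILDRLLDGYDNRLRPGLGERVTEVKTDIFVTSFGPVSDHDMEY
TIDVFFRQSWKDERLKFKGPMTVLRLNNLMASKIWTPDTFFHNGKKSVAHNMTMPNKLLR
ITEDGTLLYTMRLTVRAECPMHLEDFPMDAHACPLKFGSYAYTRAEVVYEWTREPARSVV
VAEDGSRLNQYDLLGQTVDSGIVQSSTGEYVVMTTHFHLKRKIGYFVIQTYLPCIMTVIL
SQVSFWLNRESVPARTVFGVTTVLTMTTL
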