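PDB ID	alpha1	beta2	gamma2
6X3X	4.11	4.48	5.13
6X3Z	5.16	4.56	4.52
8DD2	5.30	5.02	4.47
8DD3	5.27	5.25	4.56
8G4N	5.12	5.32	5.03
8SGO	5.05	4.68	4.26
8VQY	5.14	5.34	4.31
8VRN	5.16	5.29	4.17
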