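PDB ID	alpha1	beta2	gamma2
6X3X	6.01	5.84	5.89
6X3Z	5.91	5.83	5.87
8DD2	5.96	5.71	5.88
8DD3	5.73	5.68	5.97
8G4N	6.00	5.90	5.99
8SGO	5.95	5.80	5.90
8VQY	6.02	5.71	5.89
8VRN	5.99	5.66	5.95
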