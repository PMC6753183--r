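gene	lab_name	country	url
CDAN1	Synthetic Hematology Genetics Lab A	Spain	https://example.org/lab-a
C15orf41	Synthetic Hematology Genetics Lab A	Spain	https://example.org/lab-a
SEC23B	Synthetic Hematology Genetics Lab B	Italy	https://example.org/lab-b
SEC23B	Synthetic Erythropathy Panel Service	Germany	https://example.org/lab-c
KIF23	Synthetic Rare Anemia Reference Lab	Sweden	https://example.org/lab-d
KLF1	Synthetic Erythropathy Panel Service	Germany	https://example.org/lab-c
GATA1	Synthetic Hematology Genetics Lab B	Italy	https://example.org/lab-b
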