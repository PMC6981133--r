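chr3	0	90000000	p21	gneg
chr3	90000000	96000000	p11	acen
chr3	96000000	99000000	q11	acen
chr3	99000000	198000000	q21	gneg
chr8	0	40000000	p21	gneg
chr8	40000000	45000000	p11	acen
chr8	45000000	50000000	q11	acen
chr8	50000000	146000000	q21	gneg
chrM	0	16569	n1	gneg
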