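lp	mirna_name	sequence	sequence_length	n_reads
1	bol-miR9408	GTTTCATCTTAGAGAATGTTGTC	23	58
2	bol-miR9409	TTTTGTTCATGACTGCATTTTC	22	218
3	bol-miR9410	TACTTAATTATAAGTCGTCTGG	22	1681
4	bol-miR9411	TACTGGACGACTTACACGGAAG	22	420
5	bol-miR172a	AGAAUCUUGAUGAUGCUGCAU	21	67605
6	bol-miR157a	UUGACAGAAGAUAGAGAGCAC	21	170940
7	bna-miR166a	UCGGACCAGGCUUCAUUCCCC	21	495299
8	bra-miR167a	UGAAGCUGCCAGCAUGAUCUA	21	684250
9	bol-miR168c	UCGCUUGGUGCAGGUCGGGAA	21	128281
10	bol-miR169k*	GGCAAGUUGUCCUUCGGCUACA	22	78
11	bol-miR1885	CAUCAAUGAAAGGUAUGAUUCC	22	43
12	bol-miR403	UUAGAUUCACGCACAAACUCG	21	2170
13	bol-miR397a	UCAUUGAGUGCAGCGUUGAUGU	22	1628
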