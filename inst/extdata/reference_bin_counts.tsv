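# Published genome-wide stratification of 2403 scored genes by CGC-score
# bin: genes within arthritis QTL regions vs outside, plus the printed
# chi-square p-value per bin.  Used by the acceptance report and tests as
# a fixed reference input.
bin	n_inside	n_outside	p_printed
200 -	23	22	0.70
100 - 200	23	38	0.10
50 - 100	12	13	0.98
30 - 50	18	16	0.59
20 - 30	59	54	0.40
10 - 20	138	154	0.73
0 - 10	887	946	0.92
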