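transcript_id	gene_name	mean	minimum	maximum	sd	median
ef1a0	Elongation factor 1-alpha, somatic form	7329.9	6610.7	8457.7	586.4	7265.4
ef1b	Elongation factor 1-beta	583.4	498.6	676.9	64.3	589.4
ef1d	Elongation factor 1-delta	922.1	800.7	1074.7	98.3	910.4
ef1g-a	Elongation factor 1-gamma-A	2993.7	2611.2	3344.1	252.9	2968.2
g3pdh	Glyceraldehyde-3-phosphate dehydrogenase	1822.0	1289.5	2425.1	411.3	1768.3
rl8	60S ribosomal protein L8	1108.0	883.6	1309.3	134.8	1131.6
tuba	Tubulin alpha chain	1829.9	1589.5	2014.7	142.9	1826.3
tuba1	Tubulin alpha-1 chain	146.1	98.1	195.5	31.8	142.1
tubb	Tubulin beta chain	518.4	350.2	586.8	70.4	526.8
tubb4b	Tubulin beta-4B chain	219.0	137.1	253.7	33.3	224.5
actb	Actin, cytoplasmic 1	363.6	301.7	394.4	37.2	380.3
acta4	Actin, alpha sarcomeric/skeletal	90.1	15.1	259.4	73.3	61.9
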