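kmer	p1	p2	p3	p4	p5	p6	p7	p8	p9	p10	p11	p12
AA	35.1	-1.4	0.7	-0.03	-0.08	3.27	-7.9	-22.2	-1.00	54.50	-5.37	0.04
AC	31.5	-0.1	0.7	0.13	-0.58	3.36	-8.4	-22.4	-1.44	97.73	-10.51	0.14
AG	31.9	-1.7	4.5	0.09	-0.25	3.34	-7.8	-21.0	-1.28	58.42	-6.78	0.08
AT	29.3	0.0	1.1	0.00	-0.59	3.31	-7.2	-20.4	-0.88	57.02	-6.57	0.14
CA	37.3	0.5	4.7	0.09	0.53	3.33	-8.5	-22.7	-1.45	54.71	-6.57	0.21
CC	32.9	-0.1	3.6	0.05	-0.22	3.42	-8.0	-19.9	-1.84	85.97	-8.26	0.49
CG	36.1	0.0	5.4	0.00	0.41	3.39	-10.6	-27.2	-2.17	72.55	-9.69	0.35
CT	31.9	1.7	4.5	-0.09	-0.25	3.34	-7.8	-21.0	-1.28	58.42	-6.78	0.52
GA	36.3	-1.5	1.9	-0.28	0.09	3.37	-8.2	-22.2	-1.30	86.44	-9.81	0.10
GC	33.6	0.0	0.3	0.00	-0.38	3.40	-9.8	-24.4	-2.24	136.12	-14.59	0.26
GG	32.9	0.1	3.6	-0.05	-0.22	3.42	-8.0	-19.9	-1.84	85.97	-8.26	0.17
GT	31.5	0.1	0.7	-0.13	-0.58	3.36	-8.4	-22.4	-1.44	97.73	-10.51	0.27
TA	37.8	0.0	3.3	0.00	0.05	3.42	-7.2	-21.3	-0.58	36.73	-3.82	0.56
TC	36.3	1.5	1.9	0.28	0.09	3.37	-8.2	-22.2	-1.30	86.44	-9.81	0.87
TG	37.3	-0.5	4.7	-0.09	0.53	3.33	-8.5	-22.7	-1.45	54.71	-6.57	0.60
TT	35.1	1.4	0.7	0.03	-0.08	3.27	-7.9	-22.2	-1.00	54.50	-5.37	0.38
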