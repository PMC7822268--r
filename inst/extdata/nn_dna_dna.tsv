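# DNA:DNA unified nearest-neighbor set; dH kcal/mol, dS cal/(mol K), dG37 kcal/mol; keyed on the oligo strand 5'->3'
dimer	dH	dS	dG37
AA	-7.9	-22.2	-1.01
TT	-7.9	-22.2	-1.01
AT	-7.2	-20.4	-0.87
TA	-7.2	-21.3	-0.59
CA	-8.5	-22.7	-1.46
TG	-8.5	-22.7	-1.46
GT	-8.4	-22.4	-1.45
AC	-8.4	-22.4	-1.45
CT	-7.8	-21.0	-1.29
AG	-7.8	-21.0	-1.29
GA	-8.2	-22.2	-1.31
TC	-8.2	-22.2	-1.31
CG	-10.6	-27.2	-2.16
GC	-9.8	-24.4	-2.23
GG	-8.0	-19.9	-1.83
CC	-8.0	-19.9	-1.83
init	0.0	0.0	0.00
init_term_AT	2.3	4.1	1.03
init_term_GC	0.1	-2.8	0.97
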