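# DNA:RNA hybrid nearest-neighbor set; dH kcal/mol, dS cal/(mol K), dG37 kcal/mol; keyed on the DNA (oligo) strand 5'->3'
dimer	dH	dS	dG37
TT	-7.8	-21.9	-1.01
GT	-5.9	-12.3	-2.09
CT	-9.1	-23.5	-1.81
AT	-8.3	-23.9	-0.89
TG	-9.0	-26.1	-0.91
GG	-9.3	-23.2	-2.10
CG	-16.3	-47.1	-1.69
AG	-7.0	-19.7	-0.89
TC	-5.5	-13.5	-1.31
GC	-8.0	-17.1	-2.70
CC	-12.8	-31.9	-2.91
AC	-7.8	-21.6	-1.10
TA	-7.8	-23.2	-0.60
GA	-8.6	-22.9	-1.50
CA	-10.4	-28.4	-1.59
AA	-11.5	-36.4	-0.21
init	1.9	-3.9	3.11
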