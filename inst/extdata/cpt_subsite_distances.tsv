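row	ligand	ligand_atom	partner_res	partner_seq	partner_atom	metal	distance
1	SGlu	O16	ARG	129	NH2	NA	3.59
2	SGlu	O15	ARG	129	NH2	NA	3.54
3	SGlu	O21	ARG	129	NH1	NA	2.66
4	SGlu	O21	ARG	129	NH2	NA	3.16
5	SGlu	O15	ASN	146	ND2	NA	2.91
6	SGlu	O15	ARG	147	NH1	NA	2.80
7	SGlu	O16	ARG	147	NH2	NA	2.93
8	SGlu	N19	THR	205	O	NA	3.12
9	SGlu	N17	TYR	255	OH	NA	3.08
10	SGlu	O16	TYR	255	OH	NA	2.68
11	SGlu	N19	GLU	277	OE1	NA	3.21
12	SGlu	N17	GLU	277	OE2	NA	2.71
13	SGlu	O20	GLU	277	OE1	NA	4.03
14	SGlu	S18	NA	NA	NA	ZN	3.20
15	SGlu	O20	NA	NA	NA	ZN	4.20
16	SGlu	O21	NA	NA	NA	ZN	3.21
1	SArg	O16	ARG	129	NH2	NA	3.75
2	SArg	O15	ARG	129	NH2	NA	3.51
3	SArg	O21	ARG	129	NH1	NA	2.78
4	SArg	O21	ARG	129	NH2	NA	3.18
5	SArg	O15	ASN	146	ND2	NA	2.92
6	SArg	O15	ARG	147	NH1	NA	2.80
7	SArg	O16	ARG	147	NH2	NA	2.82
8	SArg	N19	THR	205	O	NA	3.13
9	SArg	N17	TYR	255	OH	NA	3.14
10	SArg	O16	TYR	255	OH	NA	2.71
11	SArg	N19	GLU	277	OE1	NA	3.26
12	SArg	N17	GLU	277	OE2	NA	2.71
13	SArg	O20	GLU	277	OE1	NA	4.08
14	SArg	S18	NA	NA	NA	ZN	3.18
15	SArg	O20	NA	NA	NA	ZN	4.28
16	SArg	O21	NA	NA	NA	ZN	3.31
1	SPhe	O16	ARG	129	NH2	NA	3.61
2	SPhe	O15	ARG	129	NH2	NA	3.69
3	SPhe	O21	ARG	129	NH1	NA	2.62
4	SPhe	O21	ARG	129	NH2	NA	3.28
5	SPhe	O15	ASN	146	ND2	NA	3.04
6	SPhe	O15	ARG	147	NH1	NA	2.94
7	SPhe	O16	ARG	147	NH2	NA	2.76
8	SPhe	N19	THR	205	O	NA	2.96
9	SPhe	N17	TYR	255	OH	NA	3.13
10	SPhe	O16	TYR	255	OH	NA	2.66
11	SPhe	N19	GLU	277	OE1	NA	3.30
12	SPhe	N17	GLU	277	OE2	NA	3.10
13	SPhe	O20	GLU	277	OE1	NA	4.57
14	SPhe	S18	NA	NA	NA	ZN	3.10
15	SPhe	O20	NA	NA	NA	ZN	4.10
16	SPhe	O21	NA	NA	NA	ZN	3.10
1	SLeu	O16	ARG	129	NH2	NA	3.64
2	SLeu	O15	ARG	129	NH2	NA	3.35
3	SLeu	O21	ARG	129	NH1	NA	2.68
4	SLeu	O21	ARG	129	NH2	NA	3.29
5	SLeu	O15	ASN	146	ND2	NA	3.01
6	SLeu	O15	ARG	147	NH1	NA	2.81
7	SLeu	O16	ARG	147	NH2	NA	2.83
8	SLeu	N19	THR	205	O	NA	2.97
9	SLeu	N17	TYR	255	OH	NA	3.09
10	SLeu	O15	TYR	255	OH	NA	2.64
11	SLeu	N19	GLU	277	OE1	NA	3.21
12	SLeu	N17	GLU	277	OE2	NA	2.90
13	SLeu	O20	GLU	277	OE1	NA	4.46
14	SLeu	S18	NA	NA	NA	ZN	3.08
15	SLeu	O20	NA	NA	NA	ZN	4.04
16	SLeu	O21	NA	NA	NA	ZN	3.02
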