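label	SGlu_SArg	SGlu_SPhe	SGlu_SLeu
S18	0.18	0.38	0.31
N17	0.14	0.76	0.62
N19	0.12	0.23	0.19
O20	0.26	0.65	0.57
O21	0.21	0.29	0.35
C14	0.08	0.42	0.35
O16	0.33	0.31	0.42
O15	0.04	0.34	0.21
C13	0.03	0.76	0.61
Tyr255 OH	0.21	0.44	0.75
Glu277 CD	0.05	0.54	0.39
Glu277 OE1	0.12	0.50	0.35
Glu277 OE2	0.17	1.05	0.77
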