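gene	line01	line02	line03	line04	line05	line06	line07	line08	line09	line10	line11	line12	line13	line14	line15	line16	line17	line18	line19	line20
ERG3	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0
ERG6	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	0	0
ERG5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0
ERG7	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
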