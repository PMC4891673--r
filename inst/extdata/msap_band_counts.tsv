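# Published MSAP band-type counts (926 scored loci) for the donor parent
# TTT and the seven first-selfed-generation (GS1) individuals.
# Rows: type I (unmethylated), II (CHG), III (CG), IV (CG/CHG).
type	TTT	GS1-1	GS1-2	GS1-3	GS1-4	GS1-5	GS1-6	GS1-7
I	489	503	508	509	499	497	506	491
II	140	135	134	132	134	136	132	135
III	292	283	281	280	289	288	284	295
IV	5	5	3	5	4	5	4	5
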