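gene_id	chrom	start	end	strand	is_known_imprinted	cluster
Peg12	chr7	62000000	62010000	-	TRUE	Snrpn
Magel2	chr7	62100000	62110000	-	TRUE	Snrpn
Ndn	chr7	62300000	62310000	-	TRUE	Snrpn
Mkrn3	chr7	62400000	62410000	-	TRUE	Snrpn
Snrpn	chr7	60000000	60100000	+	TRUE	Snrpn
Snhg14	chr7	59800000	60200000	+	TRUE	Snrpn
Slc22a3	chr17	12400000	12480000	+	TRUE	Airn/Igf2r
Pde10a	chr17	8500000	8800000	+	TRUE	Airn/Igf2r
Igf2r	chr17	12680000	12770000	-	TRUE	Airn/Igf2r
Tssc4	chr7	143060000	143070000	+	TRUE	Kcnq1
Ascl2	chr7	142960000	142970000	-	TRUE	Kcnq1
Kcnq1ot1	chr7	143200000	143290000	-	TRUE	Kcnq1
Cdkn1c	chr7	143450000	143460000	-	TRUE	Kcnq1
Phlda2	chr7	143480000	143490000	-	TRUE	Kcnq1
Jade1	chr3	41540000	41600000	+	TRUE	Jade1
Platr4	chr3	41700000	41710000	+	TRUE	Jade1
Sfmbt2	chr2	10310000	10540000	-	TRUE	lone
Smoc1	chr12	81100000	81280000	+	TRUE	lone
Epop	chr11	100080000	100090000	-	TRUE	lone
Spp1	chr5	104430000	104440000	+	TRUE	lone
H13	chr2	152660000	152700000	+	TRUE	lone
Etv6	chr6	134020000	134250000	+	TRUE	lone
Gatm	chr2	122590000	122610000	-	TRUE	lone
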