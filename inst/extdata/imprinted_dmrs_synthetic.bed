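chrom	start	end	name	class
chr7	60005000	60008000	Snrpn-DMR	germline_DMR
chr17	12742000	12746000	Igf2r-DMR	germline_DMR
chr7	143295000	143299000	Kcnq1ot1-DMR	germline_DMR
chr7	143100000	143103000	Kcnq1-Intergenic1	secondary_DMR
chr7	143150000	143153000	Kcnq1-Intergenic2	secondary_DMR
chr2	10400000	10403000	Sfmbt2-DMR	secondary_DMR
chr3	41560000	41563000	Jade1-DMR	secondary_DMR
chr7	62003000	62005000	Peg12-DMR	secondary_DMR
chr12	81150000	81153000	Smoc1-DMR	secondary_DMR
chr6	30740000	30743000	Peg10-DMR	germline_DMR
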