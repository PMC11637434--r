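locus_id	locus_msi	msi_1	msi_2
NR21	TRUE	TRUE	TRUE
BAT26	TRUE	TRUE	TRUE
NR27	FALSE	FALSE	FALSE
BAT25	TRUE	TRUE	FALSE
NR24	TRUE	TRUE	TRUE
NR22	FALSE	FALSE	FALSE
MONO27	FALSE	FALSE	FALSE
MS1	FALSE	FALSE	FALSE
MS4	TRUE	TRUE	TRUE
MS5	TRUE	TRUE	TRUE
MS8	FALSE	FALSE	FALSE
MS9	TRUE	TRUE	FALSE
MS10	FALSE	FALSE	FALSE
MS12	FALSE	FALSE	FALSE
MS15	TRUE	TRUE	FALSE
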