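human_symbol	mouse_symbol
PTPRC_HS	Ptprc
WAC_HS	Wac
CD44_HS	Cd44
RAD54B_HS	Rad54b
STAT5A_HS	Stat5a
SCD2_HS	Scd2
SNRPA1_HS	Snrpa1
CFLAR_HS	Cflar
TXNDC5_HS	Txndc5
FASN_HS	Fasn
PARG_HS	Parg
EIF3D_HS	Eif3d
PXDN_HS	Pxdn
EIF4G3_HS	Eif4g3
HSPA14_HS	Hspa14
GSTM2_HS	Gstm2
DUSP2_HS	Dusp2
TRAF1_HS	Traf1
YWHAZ_HS	Ywhaz
CHORDC1_HS	Chordc1
RBM14_HS	Rbm14
TUBA1B_HS	Tuba1b
SIRT5_HS	Sirt5
TCFE3_HS	Tcfe3
NAP1L1_HS	Nap1l1
ALG11_HS	Alg11
PPAN_HS	Ppan
MYST4_HS	Myst4
CD96_HS	Cd96
RUNX3_HS	Runx3
USP20_HS	Usp20
MYG1_HS	Myg1
TNFSF8_HS	Tnfsf8
PTPRC_ALIAS_HS	Ptprc
CD44_ALIAS_HS	Cd44
TRAF1_ALIAS_HS	Traf1
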