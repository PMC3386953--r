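hnRNPLL_targets	Mouse genes requiring hnRNPLL for activation-induced alternative splicing	Ptprc	Wac	Cd44	Rad54b	Stat5a	Scd2	Snrpa1	Cflar	Txndc5	Fasn	Parg	Eif3d	Pxdn	Eif4g3	Hspa14	Gstm2	Dusp2	Traf1	Ywhaz	Chordc1	Rbm14	Tuba1b	Sirt5	Tcfe3	Nap1l1	Alg11	Ppan	Myst4	Cd96	Runx3	Usp20	Myg1	Tnfsf8
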