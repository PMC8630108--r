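pair_id,ligand_genes,receptor_genes,direction
MIF_CD74,MIF,CD74,ligand_receptor
IL18_IL18R,IL18,IL18R1+IL18RAP,ligand_receptor
CD48_CD244,CD48,CD244,ligand_receptor
FAM3C_KIR2DL3,FAM3C,KIR2DL3,ligand_receptor
CD47_SIRPA,CD47,SIRPA,ligand_receptor
CD47_SIRPG,CD47,SIRPG,ligand_receptor
TNFRSF14_CD160,TNFRSF14,CD160,ligand_receptor
CLEC2B_KLRF1,CLEC2B,KLRF1,ligand_receptor
IL6_IL6R,IL6,IL6R+IL6ST,ligand_receptor
IL7_IL7R,IL7,IL7R,ligand_receptor
IL10_IL10RA,IL10,IL10RA+IL10RB,ligand_receptor
IL15_IL15RA,IL15,IL15RA,ligand_receptor
CCL2_CCR2,CCL2,CCR2,ligand_receptor
CCL3_CCR1,CCL3,CCR1,ligand_receptor
CCL4_CCR5,CCL4,CCR5,ligand_receptor
CCL5_CCR5,CCL5,CCR5,ligand_receptor
CXCL8_CXCR1,CXCL8,CXCR1,ligand_receptor
CXCL9_CXCR3,CXCL9,CXCR3,ligand_receptor
CXCL10_CXCR3,CXCL10,CXCR3,ligand_receptor
CXCL12_CXCR4,CXCL12,CXCR4,ligand_receptor
TNF_TNFRSF1A,TNF,TNFRSF1A,ligand_receptor
TNF_TNFRSF1B,TNF,TNFRSF1B,ligand_receptor
TNFSF13B_TNFRSF13B,TNFSF13B,TNFRSF13B,ligand_receptor
TNFSF13B_TNFRSF17,TNFSF13B,TNFRSF17,ligand_receptor
LGALS9_HAVCR2,LGALS9,HAVCR2,ligand_receptor
PVR_TIGIT,PVR,TIGIT,ligand_receptor
NECTIN2_CD226,NECTIN2,CD226,ligand_receptor
CD86_CTLA4,CD86,CTLA4,ligand_receptor
CD80_CD28,CD80,CD28,ligand_receptor
ICAM1_ITGAL,ICAM1,ITGAL+ITGB2,ligand_receptor
VCAM1_ITGA4,VCAM1,ITGA4+ITGB1,ligand_receptor
TGFB1_TGFBR1,TGFB1,TGFBR1+TGFBR2,ligand_receptor
IFNG_IFNGR1,IFNG,IFNGR1+IFNGR2,ligand_receptor
IL1B_IL1R1,IL1B,IL1R1,ligand_receptor
CSF1_CSF1R,CSF1,CSF1R,ligand_receptor
FLT3LG_FLT3,FLT3LG,FLT3,ligand_receptor
KITLG_KIT,KITLG,KIT,ligand_receptor
JAG1_NOTCH1,JAG1,NOTCH1,ligand_receptor
DLL1_NOTCH2,DLL1,NOTCH2,ligand_receptor
ANXA1_FPR1,ANXA1,FPR1,ligand_receptor
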