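ID   KIN1_HUMAN              Reviewed;         480 AA.
AC   P00001; Q90001; Q90002;
OS   Homo sapiens (Human).
KW   Phosphoprotein; Acetylation; Reference proteome.
FT   MOD_RES         15
FT                   /note="O-phospho-L-threonine; by AURKB"
FT   MOD_RES         88
FT                   /note="N6-acetyl-L-lysine"
SQ   SEQUENCE   480 AA;  54000 MW;  0000000000000000 CRC64;
//
ID   KIN2_HUMAN              Reviewed;         350 AA.
AC   P00002;
OS   Homo sapiens (Human).
KW   Phosphoprotein; Reference proteome.
FT   MOD_RES         42
FT                   /note="O-phospho-L-serine; by PKA"
FT   MOD_RES         77
FT                   /note="O4-phospho-L-tyrosine"
//
ID   ACT1_HUMAN              Reviewed;         375 AA.
AC   P00003;
OS   Homo sapiens (Human).
KW   Acetylation; Methylation; Reference proteome.
FT   MOD_RES         1
FT                   /note="N-acetyl-L-methionine"
FT   MOD_RES         120
FT                   /note="N6-methyl-L-lysine; alternate"
//
ID   UBC1_HUMAN              Reviewed;         153 AA.
AC   P00004;
OS   Homo sapiens (Human).
KW   Ubl conjugation; Reference proteome.
FT   CROSSLNK        48
FT                   /note="Glycyl lysine isopeptide (Lys-Gly) (interchain
FT                   with G-Cter in ubiquitin)"
//
ID   GPIA_HUMAN              Reviewed;         210 AA.
AC   P00005;
OS   Homo sapiens (Human).
KW   GPI-anchor; Glycoprotein; Reference proteome.
FT   LIPID           189
FT                   /note="GPI-anchor amidated alanine"
//
ID   BLANK_HUMAN             Reviewed;         199 AA.
AC   P00006;
OS   Homo sapiens (Human).
KW   Reference proteome; Cytoplasm.
//
ID   HIST_HUMAN              Reviewed;         130 AA.
AC   P00007;
OS   Homo sapiens (Human).
KW   Phosphoprotein; Acetylation; Reference proteome.
FT   MOD_RES         10
FT                   /note="N-acetyl-L-alanine"
FT   MOD_RES         33
FT                   /note="Phosphohistidine"
//
ID   KIN1_MOUSE              Reviewed;         478 AA.
AC   P10001;
OS   Mus musculus (Mouse).
KW   Phosphoprotein; Reference proteome.
FT   MOD_RES         15
FT                   /note="O-phospho-L-threonine"
//
ID   ACT1_MOUSE              Reviewed;         375 AA.
AC   P10002;
OS   Mus musculus (Mouse).
KW   Acetylation; Reference proteome.
FT   MOD_RES         1
FT                   /note="N-acetyl-L-methionine"
//
ID   BLANK_MOUSE             Reviewed;         200 AA.
AC   P10003;
OS   Mus musculus (Mouse).
KW   Reference proteome.
//
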