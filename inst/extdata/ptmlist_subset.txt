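----------------------------------------------------------------------------
        Controlled vocabulary of posttranslational modifications (PTM)
        Small curated subset packaged with ptmenrich for examples/tests.
        Dialect: two-letter line codes, records terminated by "//".
----------------------------------------------------------------------------
ID   O-phospho-L-threonine
AC   PTM-0255
FT   MOD_RES
TG   Threonine.
PP   Anywhere.
CF   H O3 P
MM   79.966331
MA   79.98
KW   Phosphothreonine.
DR   RESID; AA0038.
//
ID   O-phospho-L-serine
AC   PTM-0253
FT   MOD_RES
TG   Serine.
PP   Anywhere.
CF   H O3 P
MM   79.966331
MA   79.98
KW   Phosphoserine.
DR   RESID; AA0037.
//
ID   O4-phospho-L-tyrosine
AC   PTM-0257
FT   MOD_RES
TG   Tyrosine.
PP   Anywhere.
CF   H O3 P
MM   79.966331
MA   79.98
KW   Phosphotyrosine.
DR   RESID; AA0039.
//
ID   N6-acetyl-L-lysine
AC   PTM-0190
FT   MOD_RES
TG   Lysine.
PP   Anywhere.
CF   C2 H2 O
MM   42.010565
MA   42.04
KW   N6-acetyllysine.
DR   RESID; AA0055.
//
ID   N-acetyl-L-alanine
AC   PTM-0199
FT   MOD_RES
TG   Alanine.
PP   Protein N-terminus.
CF   C2 H2 O
MM   42.010565
MA   42.04
KW   N-acetylalanine.
DR   RESID; AA0041.
//
ID   N-acetyl-L-methionine
AC   PTM-0205
FT   MOD_RES
TG   Methionine.
PP   Protein N-terminus.
CF   C2 H2 O
MM   42.010565
MA   42.04
KW   N-acetylmethionine.
DR   RESID; AA0049.
//
ID   Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)
AC   PTM-0106
FT   CROSSLNK
TG   Lysine-Glycine.
PP   Anywhere.
CF   H-2 O-1
MM   -18.010565
MA   -18.02
KW   Ubl conjugation.
//
ID   GPI-anchor amidated alanine
AC   PTM-0082
FT   LIPID
TG   Alanine.
PP   Protein C-terminus.
KW   GPI-anchor.
//
ID   Phosphohistidine
AC   PTM-0244
FT   MOD_RES
TG   Histidine.
PP   Anywhere.
CF   H O3 P
MM   79.966331
MA   79.98
KW   Phosphohistidine.
//
ID   N6-methyl-L-lysine
AC   PTM-0196
FT   MOD_RES
TG   Lysine.
PP   Anywhere.
CF   C H2
MM   14.015650
MA   14.03
KW   Methyllysine.
//
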