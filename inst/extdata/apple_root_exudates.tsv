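compound_id	bound_mmol_gDW_h	name	formula	category
asn__L_e	1000	L-Asparagine	C4H8N2O3	amino_acid
asp__L_e	1000	L-Aspartate	C4H6NO4	amino_acid
cys__L_e	1000	L-Cysteine	C3H7NO2S	amino_acid
val__L_e	1000	L-Valine	C5H11NO2	amino_acid
ala_B_e	1000	beta-Alanine	C3H7NO2	amino_acid
rmn_e	1000	L-Rhamnose	C6H12O5	monosaccharide
glyc__R_e	1000	(R)-Glycerate	C3H5O4	monosaccharide
rib__D_e	1000	D-Ribose	C5H10O5	monosaccharide
gal_e	1000	D-Galactose	C6H12O6	monosaccharide
xyl__D_e	1000	D-Xylose	C5H10O5	monosaccharide
erythrs_e	1000	D-Erythrose	C4H8O4	monosaccharide
sbt__D_e	1000	D-Sorbitol	C6H14O6	sugar_alcohol
galt_e	1000	Galactitol	C6H14O6	sugar_alcohol
glyc_e	1000	Glycerol	C3H8O3	sugar_alcohol
34dhbz_e	1000	3,4-Dihydroxybenzoate	C7H5O4	other_carbohydrate
34dhcinm_e	1000	3,4-Dihydroxy-trans-cinnamate	C9H7O4	other_carbohydrate
4hbz_e	1000	4-Hydroxybenzoate	C7H5O3	other_carbohydrate
bz_e	1000	Benzoate	C7H5O2	other_carbohydrate
esculin_e	1000	Esculin	C15H16O9	other_carbohydrate
fer_e	1000	Ferulate	C10H9O4	other_carbohydrate
gallate_e	1000	Gallate	C7H5O5	other_carbohydrate
quin_e	1000	Quinate	C7H11O6	other_carbohydrate
salcn_e	1000	Salicin	C13H18O7	other_carbohydrate
cinnm_e	1000	trans-Cinnamate	C9H7O2	other_carbohydrate
galur_e	1000	D-Galacturonate	C6H10O7	organic_acid
lac__D_e	1000	D-Lactate	C3H5O3	organic_acid
mal__D_e	1000	D-Malate	C4H4O5	organic_acid
malon_e	1000	Malonate	C3H2O4	organic_acid
oxa_e	1000	Oxalate	C2O4	organic_acid
pyr_e	1000	Pyruvate	C3H3O3	organic_acid
succ_e	1000	Succinate	C4H4O4	organic_acid
urea_e	1000	Urea	CH4N2O	carbamide
ocdca_e	1000	Octadecanoate	C18H35O2	fatty_acyl
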