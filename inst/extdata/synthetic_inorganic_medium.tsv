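compound_id	bound_mmol_gDW_h	name	formula	category
h2o_e	1000	Water	H2O	water
h_e	1000	Proton	H	ion
o2_e	1000	Oxygen	O2	gas
h2_e	1000	Hydrogen	H2	gas
n2_e	1000	Dinitrogen	N2	gas
n2o_e	1000	Nitrous oxide	N2O	gas
no_e	1000	Nitric oxide	NO	gas
nh4_e	1000	Ammonium	H4N	nitrogen
nh3_e	1000	Ammonia	H3N	nitrogen
no3_e	1000	Nitrate	NO3	nitrogen
no2_e	1000	Nitrite	NO2	nitrogen
pi_e	1000	Phosphate	HO4P	phosphorus
ppi_e	1000	Diphosphate	HO7P2	phosphorus
so4_e	1000	Sulfate	O4S	sulfur
so3_e	1000	Sulfite	O3S	sulfur
h2s_e	1000	Hydrogen sulfide	H2S	sulfur
tsul_e	1000	Thiosulfate	O3S2	sulfur
s_e	1000	Elemental sulfur	S	sulfur
h2o2_e	1000	Hydrogen peroxide	H2O2	oxidant
hco3_e	1000	Bicarbonate	CHO3	inorganic_carbon
fe2_e	1000	Fe(II)	Fe	trace_metal
fe3_e	1000	Fe(III)	Fe	trace_metal
k_e	1000	Potassium	K	ion
mg2_e	1000	Magnesium	Mg	ion
ca2_e	1000	Calcium	Ca	ion
cl_e	1000	Chloride	Cl	ion
na1_e	1000	Sodium	Na	ion
zn2_e	1000	Zinc	Zn	trace_metal
mn2_e	1000	Manganese	Mn	trace_metal
cu2_e	1000	Cu(II)	Cu	trace_metal
cu_e	1000	Cu(I)	Cu	trace_metal
cobalt2_e	1000	Cobalt	Co	trace_metal
ni2_e	1000	Nickel	Ni	trace_metal
mobd_e	1000	Molybdate	MoO4	trace_metal
sel_e	1000	Selenate	O4Se	trace_metal
slnt_e	1000	Selenite	O3Se	trace_metal
tungs_e	1000	Tungstate	O4W	trace_metal
cd2_e	1000	Cadmium	Cd	trace_metal
hg2_e	1000	Mercury	Hg	trace_metal
pb2_e	1000	Lead	Pb	trace_metal
ag_e	1000	Silver	Ag	trace_metal
aso3_e	1000	Arsenite	AsO3	trace_metal
aso4_e	1000	Arsenate	AsO4	trace_metal
cro4_e	1000	Chromate	CrO4	trace_metal
vo4_e	1000	Vanadate	O4V	trace_metal
i_e	1000	Iodide	I	halide
br_e	1000	Bromide	Br	halide
f_e	1000	Fluoride	F	halide
h3bo3_e	1000	Boric acid	BH3O3	micronutrient
sio2_e	1000	Silica	O2Si	micronutrient
al3_e	1000	Aluminium	Al	ion
li_e	1000	Lithium	Li	ion
rb_e	1000	Rubidium	Rb	ion
cs_e	1000	Caesium	Cs	ion
sr2_e	1000	Strontium	Sr	ion
ba2_e	1000	Barium	Ba	ion
clo4_e	1000	Perchlorate	ClO4	ion
ti4_e	1000	Titanium	Ti	trace_metal
ws_e	1000	Tungsten(IV) sulfide	S2W	trace_metal
seo3_e	1000	Selenium dioxide	O2Se	trace_metal
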