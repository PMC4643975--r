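# model_id: toy_flat
# A small branched demonstration model in the flat tabular dialect:
# glucose feeds two routes to a biomass precursor; the upper route is
# capped, the lower route requires a two-gene complex.
[objective]
biomass
[metabolites]
id	name	compartment	chebi	boundary
glc_c	glucose	c	CHEBI:17234	0
g6p_c	glucose 6-phosphate	c	CHEBI:4170	0
pyr_c	pyruvate	c	CHEBI:15361	0
prec_c	biomass precursor	c		0
[reactions]
id	name	lb	ub	stoich
EX_glc	glucose exchange	-10	1000	glc_c=-1
HEX	hexokinase	0	1000	glc_c=-1;g6p_c=1
ROUTE_A	upper route	0	4	g6p_c=-1;prec_c=1
GLY	glycolysis lump	0	1000	g6p_c=-1;pyr_c=1
ROUTE_B	lower route	0	1000	pyr_c=-1;prec_c=1
biomass	biomass drain	0	1000	prec_c=-1
[gpr]
reaction_id	gpr
HEX	(YFR053C or YGL253W)
ROUTE_A	YAL012W
GLY	YCR012W
ROUTE_B	(YGR155W and YLR058C)
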