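name	edits	provenance	description
P9Am1	A32-A34:KR>MLE	fully_specified	MLE insertion closing the aKRAB gap: gap+KR at A32-A34 replaced by the conserved MLE motif (+1 residue)
P9Am2		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am3		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am4		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am5		figure_dependent	13 amino acid changes in total; composition defined only graphically
P9Am6		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am7		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am8		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am9		figure_dependent	intermediate construct; residue composition defined only graphically
P9Am10	A9:S>F;A20:M>L;A27:R>V;A32-A34:KR>MLE	fully_specified	minimal fully active configuration: MLE insertion plus F9, L20, V27
P9Am11	A9:S>F;A27:R>V;A32-A34:KR>MLE	fully_specified	P9Am10 with L20 reverted to the original M20
P9Am12	A9:S>F;A32-A34:KR>MLE	fully_specified	P9Am11 with V27 reverted to the original R27
P9Am13	A9:S>F;A20:M>L;A27:R>V	fully_specified	P9Am10 with the MLE insertion mutated back to gap-KR (wild-type-relative form)
ZNF10Am1	A10-A12:FVD>SIY	fully_specified	ZNF10-A with residues 10-12 switched from FVD to the PRDM9 original SIY
ZNF10-PP	A33-A33:L>LPP	fully_specified	double-proline helix breaker inserted before E34 (block form keeps edits non-overlapping)
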