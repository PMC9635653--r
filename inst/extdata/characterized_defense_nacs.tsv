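subfamily	species	gene_id	gene_name	defense_role	genetic_evidence
a	Triticum aestivum	TraesCS5A02G468300	TaNAC002-A1	Suppressed resistance to Puccinia striiformis f. sp. tritici	VIGS
a	Triticum aestivum	TraesCS3A02G406000	TaNAC048-A1	Enhanced resistance to Blumeria graminis	Overexpression and VIGS
a	Triticum aestivum	TraesCS3B02G439600	TaNAC048-B1	Enhanced resistance to Blumeria graminis	VIGS
a	Triticum aestivum	TraesCS3D02G401200	TaNAC048-D1	Enhanced resistance to Blumeria graminis	VIGS
a	Triticum aestivum	TraesCS3B02G194000	TaNAC160-B1	Enhanced resistance to Fusarium graminearum	VIGS
a	Hordeum vulgare	HORVU1Hr1G063740	HvNAC6	Enhanced resistance to Blumeria graminis	Overexpression, VIGS, RNAi
a	Hordeum vulgare	HORVU5Hr1G111590	HvSNAC1	Enhanced resistance to Ramularia collo-cygni	Overexpression
a	Oryza sativa	Os11g0126900	ONAC122	Enhanced resistance to Magnaporthe oryzae	VIGS
a	Oryza sativa	Os12g0123700	ONAC131	Enhanced resistance to Magnaporthe oryzae	VIGS
a	Oryza sativa	Os01g0884300	ONAC048	Enhanced resistance to Magnaporthe oryzae	Overexpression
a	Arabidopsis thaliana	At1g01720	ANAC002	Enhanced resistance to Blumeria graminis; modulation of Botrytis and Pseudomonas resistance	T-DNA insertion, overexpression
a	Arabidopsis thaliana	At5g08790	ANAC081	Suppressed resistance to Botrytis cinerea	Overexpression
a	Arabidopsis thaliana	At1g52890	ANAC019	Suppressed resistance to Fusarium oxysporum and Pseudomonas syringae pv. maculicola	T-DNA insertion, overexpression
a	Arabidopsis thaliana	At3g15500	ANAC055	Suppressed resistance to Fusarium oxysporum and Pseudomonas syringae pv. maculicola	T-DNA insertion, overexpression
a	Arabidopsis thaliana	At4g27410	ANAC072	Suppressed resistance to Pseudomonas syringae pv. maculicola	T-DNA insertion
b	Oryza sativa	Os03g0119966	ONAC054	Conferred susceptibility to Rice Dwarf Virus	Tos17 insertion, overexpression
b	Arabidopsis thaliana	At5g24590	ANAC091	Conferred resistance to Turnip Crinkle Virus	Resistant inbred line
b	Arabidopsis thaliana	At3g49530	ANAC062	Enhanced resistance to Pseudomonas syringae pv. tomato DC3000	Overexpression of truncated form, RNAi
b	Arabidopsis thaliana	At4g35580	NTL9	Suppressed resistance to Pseudomonas syringae pv. tomato DC3000	T-DNA insertion
c	Triticum aestivum	TraesCS2D02G576400	TaNAC031-D3-2	Suppressed resistance to Puccinia striiformis f. sp. tritici	VIGS
d	Triticum aestivum	TraesCS5B02G054200	TaNAC060-B1	Suppressed resistance to Puccinia striiformis f. sp. tritici	VIGS
d	Triticum aestivum	TraesCS7A02G305200	TaNAC104-A2	Suppressed resistance to Puccinia striiformis and Pseudomonas syringae	VIGS, ectopic overexpression
d	Oryza sativa	Os12g0610600	ONAC060	Enhanced resistance to Magnaporthe oryzae	RNAi
d	Arabidopsis thaliana	At5g39610	ANAC092	Age-related resistance to Hyaloperonospora parasitica	T-DNA insertion
e	Triticum aestivum	TraesCS3D02G398200	TaNAC075-D1	Suppressed resistance to Puccinia triticina	VIGS
e	Oryza sativa	Os11g0154500	ONAC017	Enhanced resistance to Magnaporthe oryzae	Overexpression
e	Oryza sativa	Os03g0777000	ONAC066	Enhanced resistance to Magnaporthe oryzae and Xanthomonas oryzae	Overexpression
h	Triticum aestivum	TraesCS5D02G111300	TaNAC175-D1	Enhanced resistance to Fusarium graminearum	Overexpression
unknown	Arabidopsis thaliana	At5g64530	ANAC104	Enhanced resistance to Ralstonia solanacearum	T-DNA insertion, complementation
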