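# oncopanel actionability knowledge-base snapshot
# kb_version=2026-09 (static snapshot; breast-cancer indication)
alteration_kind	gene	protein_change	therapy	evidence_note
variant_hotspot	PIK3CA	p.Asn345Lys	PI3Ka inhibitor (alpelisib) + ER antagonist (fulvestrant)	HR-positive HER2-negative breast cancer, FDA-approved combination
variant_hotspot	PIK3CA	p.Glu545Lys	PI3Ka inhibitor (alpelisib) + ER antagonist (fulvestrant)	HR-positive HER2-negative breast cancer, FDA-approved combination
variant_hotspot	PIK3CA	p.His1047Arg	PI3Ka inhibitor (alpelisib) + ER antagonist (fulvestrant)	HR-positive HER2-negative breast cancer, FDA-approved combination
variant_hotspot	PIK3CA	p.His1047Leu	PI3Ka inhibitor (alpelisib) + ER antagonist (fulvestrant)	HR-positive HER2-negative breast cancer, FDA-approved combination
variant_hotspot	PIK3CA	p.Gly1049Arg	PI3Ka inhibitor (alpelisib) + ER antagonist (fulvestrant)	HR-positive HER2-negative breast cancer, FDA-approved combination
germline_gene	BRCA1	NA	PARP inhibitor (olaparib, talazoparib)	Pathogenic germline variant, with or without biallelic loss
germline_gene	BRCA2	NA	PARP inhibitor (olaparib, talazoparib)	Pathogenic germline variant, with or without biallelic loss
germline_gene	PALB2	NA	PARP inhibitor (olaparib, talazoparib)	Pathogenic germline variant, with or without biallelic loss
tmb_high	NA	NA	Immune checkpoint inhibitor (pembrolizumab)	Tumor mutational burden >= 10 mut/Mb
msi_high	NA	NA	Immune checkpoint inhibitor (pembrolizumab)	Microsatellite instability-high phenotype
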