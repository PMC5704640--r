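# positive_class: lymphoma
# negative_class: breast_cancer
# Three-pair majority-vote signature discriminating lymphoma from breast
# cancer tissue. direction_positive = +1 means gene_i is the
# higher-expressed gene of the pair in lymphoma (the positive class); in
# breast cancer each pair's ordering is reversed. Training rank
# differences are not shipped (NA), so this fixture cannot be
# rank-difference filtered.
gene_i	gene_j	direction_positive	degree	mean_rank_diff_pos	mean_rank_diff_neg
MMP3	RGS13	-1	NA	NA	NA
CD37	EPCAM	1	NA	NA	NA
EPCAM	STAP1	-1	NA	NA	NA
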