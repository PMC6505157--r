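quantity	value
mapped_scaffolds	14336
multi_marker_scaffolds	4859
inter_split	164
intra_split	26
splits_total	219
splits_at_join	184
total_markers	21056
gene_models_anchored	17079
cluster_totals_observed_cM_1	3389.4
cluster_totals_estimated_cM_1	2294.2
cluster_totals_bins_1	3924
cluster_totals_observed_cM_2	4143.4
cluster_totals_estimated_cM_2	2478.3
cluster_totals_bins_2	5311
cluster_totals_observed_cM_3	3706.7
cluster_totals_estimated_cM_3	1971.0
cluster_totals_bins_3	11479
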