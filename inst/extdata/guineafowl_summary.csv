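group,category,n_interactions,group_size,n_per_individual,rs
1,higher_cost_aggressive,1229,23,53,0.96
1,lower_cost_aggressive,1558,23,68,0.93
1,submissive,2628,23,114,0.95
2,higher_cost_aggressive,627,29,22,0.91
2,lower_cost_aggressive,529,29,18,0.91
2,submissive,787,29,27,0.93
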