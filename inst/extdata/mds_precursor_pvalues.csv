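feature,p_blast_atypical,p_atypical_promyelocyte,p_global,published_label
area,0.95,0.37,0.60,not_defined
perimeter,0.01,0.004,0.00001,intermediate
form_factor,0.0001,0.0005,0.0001,intermediate
mean_gray,0.0009,0.0227,0.00001,intermediate
sd_gray,0.0001,0.02,0.01,intermediate
entropy,0.11,0.083,0.01,not_defined
inertia,0.0038,0.095,0.0001,close_to_promyelocytes
local_homogeneity,0.32,0.23,0.12,not_defined
energy,0.00003,0.39,0.0001,close_to_promyelocytes
contrast,0.0038,0.095,0.0001,close_to_promyelocytes
diagonal_moment,0.00058,0.098,0.0001,close_to_promyelocytes
cluster_prominence,0.021,0.51,0.018,close_to_promyelocytes
fd_minkowski,0.0015,0.82,0.0015,close_to_promyelocytes
fd_r2,0.026,0.65,0.068,not_defined
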