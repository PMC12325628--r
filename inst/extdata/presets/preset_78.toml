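age = 78

[generator]
n_fibers = 1070
diameter_mean = 3.36
diameter_sd = 0.15
length_mean = 22.5249
length_sd = 7.5083
vertical_fraction = 0.0963
waviness = 0.04
cluster_sizes = [303, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 16, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15]
seed = 78

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.36
fiber_count = 1070
volume_fraction_pct = 2.32
n_clusters = 51
max_cluster_size = 303
vertical_proportion_pct = 9.63
firmness = 0.0000
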