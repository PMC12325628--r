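age = 43

[generator]
n_fibers = 2183
diameter_mean = 3.68
diameter_sd = 0.15
length_mean = 20.2285
length_sd = 6.7428
vertical_fraction = 0.1851
waviness = 0.04
cluster_sizes = [2127, 6, 6, 6, 6, 6, 6, 5, 5, 5, 5]
seed = 43

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.68
fiber_count = 2183
volume_fraction_pct = 5.26
n_clusters = 11
max_cluster_size = 2127
vertical_proportion_pct = 18.51
firmness = 0.8370
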