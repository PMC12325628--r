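age = 49

[generator]
n_fibers = 2056
diameter_mean = 3.59
diameter_sd = 0.15
length_mean = 13.7310
length_sd = 4.5770
vertical_fraction = 0.3248
waviness = 0.04
cluster_sizes = [1642, 16, 16, 16, 16, 16, 16, 16, 16, 16, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15]
seed = 49

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.59
fiber_count = 2056
volume_fraction_pct = 3.26
n_clusters = 28
max_cluster_size = 1642
vertical_proportion_pct = 32.48
firmness = 0.5330
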