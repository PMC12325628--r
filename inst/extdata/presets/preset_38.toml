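age = 38

[generator]
n_fibers = 2437
diameter_mean = 3.86
diameter_sd = 0.15
length_mean = 12.8852
length_sd = 4.2951
vertical_fraction = 0.2544
waviness = 0.04
cluster_sizes = [2415, 6, 6, 5, 5]
seed = 38

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.86
fiber_count = 2437
volume_fraction_pct = 4.23
n_clusters = 5
max_cluster_size = 2415
vertical_proportion_pct = 25.44
firmness = 1.0000
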