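age = 59

[generator]
n_fibers = 1713
diameter_mean = 3.52
diameter_sd = 0.15
length_mean = 19.9000
length_sd = 6.6333
vertical_fraction = 0.1640
waviness = 0.04
cluster_sizes = [1070, 36, 36, 36, 36, 36, 36, 36, 36, 36, 36, 36, 36, 36, 35, 35, 35, 35, 35]
seed = 59

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.52
fiber_count = 1713
volume_fraction_pct = 3.63
n_clusters = 19
max_cluster_size = 1070
vertical_proportion_pct = 16.40
firmness = 0.3180
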