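age = 70

[generator]
n_fibers = 1352
diameter_mean = 3.37
diameter_sd = 0.15
length_mean = 16.5355
length_sd = 5.5118
vertical_fraction = 0.1731
waviness = 0.04
cluster_sizes = [626, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 19, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18, 18]
seed = 70

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.37
fiber_count = 1352
volume_fraction_pct = 2.25
n_clusters = 40
max_cluster_size = 626
vertical_proportion_pct = 17.31
firmness = 0.0440
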