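age = 58

[generator]
n_fibers = 2081
diameter_mean = 3.45
diameter_sd = 0.15
length_mean = 19.6346
length_sd = 6.5449
vertical_fraction = 0.2686
waviness = 0.04
cluster_sizes = [1883, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6]
seed = 58

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.45
fiber_count = 2081
volume_fraction_pct = 4.18
n_clusters = 32
max_cluster_size = 1883
vertical_proportion_pct = 26.86
firmness = 0.3010
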