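age = 39

[generator]
n_fibers = 1060
diameter_mean = 3.54
diameter_sd = 0.15
length_mean = 19.6251
length_sd = 6.5417
vertical_fraction = 0.2830
waviness = 0.04
cluster_sizes = [795, 17, 17, 17, 17, 17, 17, 17, 17, 17, 16, 16, 16, 16, 16, 16, 16]
seed = 39

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.54
fiber_count = 1060
volume_fraction_pct = 2.34
n_clusters = 17
max_cluster_size = 795
vertical_proportion_pct = 28.30
firmness = 0.1550
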