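age = 67

[generator]
n_fibers = 804
diameter_mean = 3.35
diameter_sd = 0.15
length_mean = 30.5626
length_sd = 10.1875
vertical_fraction = 0.0622
waviness = 0.04
cluster_sizes = [248, 13, 13, 13, 13, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12]
seed = 67

[domain]
size_x = 343.57
size_y = 250
size_z = 99.75

[targets]
mean_fiber_diameter_um = 3.35
fiber_count = 804
volume_fraction_pct = 2.28
n_clusters = 47
max_cluster_size = 248
vertical_proportion_pct = 6.22
firmness = 0.0256
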