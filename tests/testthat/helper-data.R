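# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Well-separated K-class Gaussian mixture: accuracy ~1 for any classifier.
separable_dataset <- function(n_per_class = 10, K = 3, dims = 2, seed = 1,
                              radius = 10) {
  generate_feature_table(n_per_class, default_class_means(K, dims, radius),
                         noise_sd = 1, seed = seed)
}

# Moderately overlapping mixture (accuracy well below 1, above chance).
overlap_dataset <- function(n_per_class = 50, K = 3, dims = 2, seed = 1) {
  generate_feature_table(n_per_class, default_class_means(K, dims, radius = 2),
                         noise_sd = 1, seed = seed)
}

# Minimal recording with known content.
toy_recording <- function(values, sampling_rate = 1, baseline_window = 1:2) {
  sensor_recording(matrix(values, ncol = 1), sampling_rate,
                   baseline_window = baseline_window, sample_id = "toy")
}
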