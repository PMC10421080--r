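# Builders for small in-memory fixtures used across the suite.

# A feature table seeded with genuine pairs, near-miss pairs and random
# background, with offsets drawn to straddle the default tolerances so the
# windowed join and the exhaustive oracle are exercised at the boundaries.
random_boundary_table <- function(n_peaks = 200, seed = 1,
                                  tag = propanoyl_tag()) {
  withr::with_seed(seed, {
    n_pairs <- floor(n_peaks / 4)
    base_mz <- runif(n_pairs, 150, 1000)
    base_rt <- runif(n_pairs, 1, 40)
    base_int <- rlnorm(n_pairs, log(1e5), 1)
    ppm_off <- runif(n_pairs, -6, 6)        # straddles +/-3 ppm
    rt_off <- runif(n_pairs, -0.1, 0.1)     # straddles +/-0.05 min
    ratio <- runif(n_pairs, 0.3, 1.7)       # straddles 33% intensity diff
    heavy_mz <- (base_mz + tag$pair_delta) * (1 + ppm_off * 1e-6)
    n_bg <- n_peaks - 2 * n_pairs
    peaks <- data.frame(
      mz = c(base_mz, heavy_mz, runif(n_bg, 150, 1005)),
      rt = c(base_rt, base_rt + rt_off, runif(n_bg, 1, 40)),
      intensity = c(base_int, base_int * ratio, rlnorm(n_bg, log(1e5), 1)))
    peak_table(peaks[sample.int(nrow(peaks)), ], sample_label = "rnd")
  })
}

hit_keys <- function(ht) {
  h <- ht$hits
  sort(paste(h$light_id, h$heavy_id, h$n_tags, sep = "|"))
}

# Hand-built hit table with one hit per supplied light m/z, RT.
toy_hit_table <- function(light_mz, light_rt, sample_label = "toy",
                          role = "other", tag = propanoyl_tag()) {
  k <- length(light_mz)
  hit_table(data.frame(
    light_id = sprintf("%s_L%03d", sample_label, seq_len(k)),
    heavy_id = sprintf("%s_H%03d", sample_label, seq_len(k)),
    light_mz = light_mz, heavy_mz = light_mz + tag$pair_delta,
    light_rt = light_rt, heavy_rt = light_rt,
    light_intensity = 1e5, heavy_intensity = 1e5,
    n_tags = 1L, ppm_error = 0, rt_delta = 0, intensity_rel_diff = 0,
    inferred_parent_mz = light_mz - tag$light_addition,
    stringsAsFactors = FALSE), sample_label = sample_label, role = role)
}
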