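test_that("a textbook twin peak is detected with its quality metrics", {
  pt <- peak_table(data.frame(mz = c(500.0000, 503.0101),
                              rt = c(10.00, 10.01),
                              intensity = c(1.0e5, 0.9e5)))
  ht <- find_labeled_pairs(pt)
  expect_equal(n_hits(ht), 1L)
  h <- ht$hits
  expect_equal(h$n_tags, 1L)
  expect_equal(h$ppm_error, 0.07, tolerance = 0.01)
  expect_equal(h$rt_delta, 0.01)
  expect_equal(h$intensity_rel_diff, 0.1)
  expect_gt(h$heavy_mz, h$light_mz)
})

test_that("each tolerance individually vetoes a candidate pair", {
  base <- data.frame(mz = c(500.0000, 503.0101), rt = c(10.00, 10.01),
                     intensity = c(1.0e5, 0.9e5))
  too_dim <- transform(base, intensity = c(1.0e5, 0.5e5))    # 50% > 33%
  drifted <- transform(base, rt = c(10.00, 10.20))           # 0.2 > 0.05 min
  off_mass <- transform(base, mz = c(500.0000, 503.0150))    # ~10 ppm off
  expect_equal(n_hits(find_labeled_pairs(peak_table(too_dim))), 0L)
  expect_equal(n_hits(find_labeled_pairs(peak_table(drifted))), 0L)
  expect_equal(n_hits(find_labeled_pairs(peak_table(off_mass))), 0L)
})

test_that("degenerate tables give empty hit tables", {
  empty <- peak_table(data.frame(mz = numeric(), rt = numeric(),
                                 intensity = numeric()))
  single <- peak_table(data.frame(mz = 500, rt = 10, intensity = 1e5))
  expect_equal(n_hits(find_labeled_pairs(empty)), 0L)
  expect_equal(n_hits(find_labeled_pairs(single)), 0L)
  expect_equal(n_hits(brute_force_pairs(empty)), 0L)
  expect_equal(n_hits(brute_force_pairs(single)), 0L)
})

test_that("windowed join and exhaustive oracle agree on boundary-rich tables", {
  policies <- list(tolerance_policy(),
                   tolerance_policy(mz_ppm = 10, rt_window = 0.2,
                                    intensity_max_rel_diff = 0.8),
                   tolerance_policy(mz_ppm = 1, rt_window = 0.02,
                                    intensity_max_rel_diff = 0.1),
                   tolerance_policy(n_tags = 1:2))
  for (seed in 1:30) {
    pt <- random_boundary_table(150, seed = seed)
    pol <- policies[[(seed %% length(policies)) + 1L]]
    expect_identical(hit_keys(find_labeled_pairs(pt, policy = pol)),
                     hit_keys(brute_force_pairs(pt, policy = pol)),
                     info = paste("seed", seed))
  }
})

test_that("the hit set is invariant under row permutation", {
  pt <- random_boundary_table(200, seed = 5)
  ref <- find_labeled_pairs(pt)
  for (seed in 1:5) {
    shuffled <- withr::with_seed(seed, {
      peak_table(pt$peaks[sample.int(nrow(pt$peaks)), ])
    })
    expect_identical(hit_keys(find_labeled_pairs(shuffled)), hit_keys(ref))
  }
})

test_that("hits are monotone in every tolerance", {
  pt <- random_boundary_table(200, seed = 9)
  narrow <- tolerance_policy(mz_ppm = 1.5, rt_window = 0.02,
                             intensity_max_rel_diff = 0.15)
  default <- tolerance_policy()
  wide <- tolerance_policy(mz_ppm = 8, rt_window = 0.1,
                           intensity_max_rel_diff = 0.6)
  k_narrow <- hit_keys(find_labeled_pairs(pt, policy = narrow))
  k_default <- hit_keys(find_labeled_pairs(pt, policy = default))
  k_wide <- hit_keys(find_labeled_pairs(pt, policy = wide))
  expect_true(all(k_narrow %in% k_default))
  expect_true(all(k_default %in% k_wide))
})

test_that("a natural isotope envelope alone is not reported as a pair", {
  # M+0..M+3 of an untagged compound at 13C spacing: the M+3 satellite sits
  # at the right m/z but at ~1% relative intensity, so the intensity filter
  # rejects it by an order of magnitude.
  spacing <- element_masses()[["C13"]] - element_masses()[["C12"]]
  env <- data.frame(mz = 500.25 + (0:3) * spacing,
                    rt = 12.0,
                    intensity = 1e6 * c(1, 0.30, 0.06, 0.01))
  expect_equal(n_hits(find_labeled_pairs(peak_table(env))), 0L)
})

test_that("deduplication keeps the best hit per light peak", {
  tag <- propanoyl_tag()
  # one light, two candidate heavies at ~0.1 and ~2.9 ppm
  pt <- peak_table(data.frame(
    mz = c(500, (500 + tag$pair_delta) * (1 + 0.1e-6),
           (500 + tag$pair_delta) * (1 + 2.9e-6)),
    rt = c(10, 10.01, 10.02), intensity = c(1e5, 1e5, 1e5)))
  all_hits <- find_labeled_pairs(pt)
  expect_equal(n_hits(all_hits), 2L)
  expect_identical(deduplicate_hits(all_hits, "keep_all")$hits, all_hits$hits)
  best <- deduplicate_hits(all_hits, "best_ppm")
  expect_equal(n_hits(best), 1L)
  expect_equal(abs(best$hits$ppm_error), 0.1, tolerance = 0.02)

  # exact ppm tie resolved by smaller |rt_delta|
  pt2 <- peak_table(data.frame(
    mz = c(500, 500 + tag$pair_delta, 500 + tag$pair_delta + 1e-9),
    rt = c(10, 10.00, 10.04), intensity = c(1e5, 1e5, 1e5)))
  best2 <- deduplicate_hits(find_labeled_pairs(pt2), "best_ppm")
  expect_equal(best2$hits$rt_delta, 0)
  expect_error(deduplicate_hits(all_hits, "random"), "arg")
})

test_that("policy validation rejects out-of-range tolerances", {
  expect_error(tolerance_policy(mz_ppm = 0), "positive")
  expect_error(tolerance_policy(intensity_max_rel_diff = 1.5), "0, 1")
  expect_error(tolerance_policy(n_tags = 0), "positive")
  expect_error(find_labeled_pairs(random_boundary_table(20, 1),
                                  policy = tolerance_policy(n_tags = 5)),
               "max_tags")
})
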