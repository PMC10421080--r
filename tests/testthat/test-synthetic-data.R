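test_that("the generator is deterministic in its seed", {
  s <- synthetic_spec(n_tagged_compounds = 40, n_background = 100, seed = 5)
  a <- generate_extract_tables(s)
  b <- generate_extract_tables(s)
  expect_identical(a$pre$peaks, b$pre$peaks)
  expect_identical(a$post$peaks, b$post$peaks)
  expect_identical(a$truth, b$truth)
  c <- generate_extract_tables(synthetic_spec(n_tagged_compounds = 40,
                                              n_background = 100, seed = 6))
  expect_false(identical(a$pre$peaks, c$pre$peaks))
  # the generator restores the caller's RNG state
  withr::with_seed(1, {
    before <- runif(1)
    set.seed(1); runif(0)
    invisible(generate_extract_tables(s))
    expect_identical(runif(1), before)
  })
})

test_that("tagged compounds emit exactly one light and one heavy peak", {
  s <- synthetic_spec(n_tagged_compounds = 50, n_background = 80,
                      n_metabolite_only = 3, seed = 8)
  tabs <- generate_extract_tables(s)
  tagged <- grepl("^cmpd", tabs$pre$peaks$peak_id)
  expect_equal(sum(tagged), 100L)
  expect_equal(nrow(tabs$truth), 53L)
  expect_equal(sum(!tabs$truth$metabolite_only), 50L)
  # every emitted tagged peak traces to exactly one compound
  expect_true(all(tabs$truth$light_id[!tabs$truth$metabolite_only] %in%
                    tabs$pre$peaks$peak_id))
  expect_true(all(tabs$truth$heavy_id[!tabs$truth$metabolite_only] %in%
                    tabs$pre$peaks$peak_id))
  # metabolite-only pairs appear post, never pre
  met <- tabs$truth[tabs$truth$metabolite_only, ]
  expect_false(any(met$light_id %in% tabs$pre$peaks$peak_id))
  expect_true(all(met$light_id %in% tabs$post$peaks$peak_id))
  # binders (and only binders) carry their pair into the post table
  binders <- tabs$truth[tabs$truth$binder & !tabs$truth$metabolite_only, ]
  nonbind <- tabs$truth[!tabs$truth$binder, ]
  expect_true(all(binders$light_id %in% tabs$post$peaks$peak_id))
  expect_false(any(nonbind$light_id %in% tabs$post$peaks$peak_id))
})

test_that("a noiseless, decoy-free table is recovered exactly", {
  s <- synthetic_spec(n_tagged_compounds = 50, n_background = 200,
                      mz_jitter_ppm = 0, rt_jitter_min = 0,
                      intensity_log_sd = 0, envelope_decoys = FALSE,
                      seed = 12)
  tabs <- generate_extract_tables(s)
  hits <- find_labeled_pairs(tabs$pre)
  expect_equal(n_hits(hits), 50L)
  m <- evaluate_detection(hits, tabs$truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
})

test_that("detection metrics count hits against the ground truth", {
  tabs <- generate_extract_tables(synthetic_spec(n_tagged_compounds = 20,
                                                 n_background = 50,
                                                 seed = 14))
  empty <- hit_table(role = "pre_binding")
  m0 <- evaluate_detection(empty, tabs$truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$fn, 20L)
  # a fabricated wrong pair counts as a false positive
  fake <- toy_hit_table(light_mz = 400, light_rt = 5)
  mf <- evaluate_detection(fake, tabs$truth, role = "pre_binding")
  expect_equal(mf$fp, 1L)
  # post-role evaluation expects binders plus metabolite-only pairs
  post_hits <- find_labeled_pairs(tabs$post)
  mp <- evaluate_detection(post_hits, tabs$truth)
  n_expected <- sum(tabs$truth$binder | tabs$truth$metabolite_only)
  expect_equal(mp$tp + mp$fn, n_expected)
})

test_that("background envelopes have the advertised satellite structure", {
  s <- synthetic_spec(n_tagged_compounds = 0, n_background = 30,
                      mz_jitter_ppm = 0, rt_jitter_min = 0, seed = 17)
  tabs <- generate_extract_tables(s)
  p <- tabs$pre$peaks
  m0 <- p[grepl("^bg\\d+$", p$peak_id), ]
  m3 <- p[grepl("_M3$", p$peak_id), ]
  expect_equal(nrow(m0), 30L)
  expect_equal(nrow(m3), 30L)
  spacing <- element_masses()[["C13"]] - element_masses()[["C12"]]
  ord0 <- match(sub("_M3$", "", m3$peak_id), m0$peak_id)
  expect_equal(m3$mz, m0$mz[ord0] + 3 * spacing, tolerance = 1e-9)
  rel <- m3$intensity / m0$intensity[ord0]
  expect_true(all(rel >= 0.005 & rel <= 0.015))
})

test_that("invalid specifications are rejected per field", {
  expect_error(synthetic_spec(binder_fraction = 1.5), "binder_fraction")
  expect_error(synthetic_spec(mz_range = c(500, 100)), "mz_range")
  expect_error(synthetic_spec(rt_range = c(-1, 10)), "rt_range")
  expect_error(synthetic_spec(mz_jitter_ppm = -1), "jitter")
})
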