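# Seeded simulation of pre/post feature tables with full ground truth.
#
# The generator emulates what the tagging chemistry and the cell-affinity
# assay put in front of the data analysis: every tagged compound contributes
# a co-eluting light/heavy twin peak with near-1:1 intensity; untagged
# background features carry natural isotope envelopes whose M+3 satellite is
# the decoy the intensity filter has to reject; a small fraction of tagged
# compounds ("binders") survives into the post table, together with fresh
# cell background and a few metabolite-only pairs.

#' Specification for a synthetic pre/post screening experiment
#'
#' Defaults describe a single crude-extract screening run: a few hundred
#' successfully tagged compounds among thousands of untagged features, with
#' Orbitrap-class measurement noise and a binder fraction in the few-percent
#' regime typical of whole-cell affinity enrichment.
#'
#' @param n_tagged_compounds Number of tagged compounds (each emits one
#'   light and one heavy peak in the pre table).
#' @param n_background Number of untagged background features per table.
#' @param binder_fraction Fraction of tagged compounds surviving to the post
#'   table; the number of binders is `round(n_tagged_compounds *
#'   binder_fraction)`.
#' @param mz_range Range (Th) the untagged parent m/z values are drawn from.
#' @param rt_range Retention-time range in minutes.
#' @param mz_jitter_ppm Standard deviation of the per-peak mass error (ppm).
#' @param rt_jitter_min Standard deviation of the per-peak RT error (min).
#' @param intensity_log_sd Standard deviation of the log-normal light/heavy
#'   intensity imbalance (1:1 tagging; isotopologues co-elute and ionize
#'   alike, so only ion-statistics noise separates them).
#' @param envelope_decoys Emit M+1/M+2/M+3 natural-isotope satellites for
#'   background features (relative intensities ~20-35%, 3-8%, 0.5-1.5% of
#'   M+0, spaced by m(13C) - m(12C)).
#' @param post_attenuation Intensity scale applied to binder compounds in
#'   the post table (washing and lysis lose material).
#' @param n_metabolite_only Tagged pairs present only in the post table
#'   (cell-metabolized products).
#' @param seed Integer seed; the generator uses the Mersenne-Twister RNG
#'   with inversion normals, so identical specs give identical tables on
#'   every platform.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tagged_compounds = 300L,
                           n_background = 3000L,
                           binder_fraction = 0.08,
                           mz_range = c(150, 1200),
                           rt_range = c(0.5, 45),
                           mz_jitter_ppm = 0.5,
                           rt_jitter_min = 0.005,
                           intensity_log_sd = 0.1,
                           envelope_decoys = TRUE,
                           post_attenuation = 0.4,
                           n_metabolite_only = 5L,
                           seed = 1L) {
  stopifnot(n_tagged_compounds >= 0, n_background >= 0,
            n_metabolite_only >= 0)
  if (binder_fraction < 0 || binder_fraction > 1)
    stop("binder_fraction must lie in [0, 1]")
  if (length(mz_range) != 2L || diff(mz_range) <= 0 || mz_range[1] <= 0)
    stop("mz_range must be an increasing positive pair")
  if (length(rt_range) != 2L || diff(rt_range) <= 0 || rt_range[1] < 0)
    stop("rt_range must be an increasing non-negative pair")
  if (mz_jitter_ppm < 0 || rt_jitter_min < 0 || intensity_log_sd < 0)
    stop("jitter parameters must be non-negative")
  if (post_attenuation <= 0) stop("post_attenuation must be positive")
  structure(list(n_tagged_compounds = as.integer(n_tagged_compounds),
                 n_background = as.integer(n_background),
                 binder_fraction = binder_fraction,
                 mz_range = as.numeric(mz_range),
                 rt_range = as.numeric(rt_range),
                 mz_jitter_ppm = mz_jitter_ppm,
                 rt_jitter_min = rt_jitter_min,
                 intensity_log_sd = intensity_log_sd,
                 envelope_decoys = isTRUE(envelope_decoys),
                 post_attenuation = post_attenuation,
                 n_metabolite_only = as.integer(n_metabolite_only),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 13C isotope spacing of natural envelopes; identical to pair_delta / 3.
.C13_SPACING <- 13.003354835 - 12.0

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

.jitter_mz <- function(mz, ppm_sd) mz * (1 + stats::rnorm(length(mz), 0, ppm_sd) * 1e-6)

# Observed light/heavy peak rows for a set of compounds.
.emit_pairs <- function(ids, parent_mz, rt, base_int, spec, tag,
                        attenuation = 1) {
  k <- length(ids)
  if (k == 0L) {
    return(data.frame(peak_id = character(), mz = numeric(), rt = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  }
  light_true <- parent_mz + tag$light_addition
  heavy_true <- parent_mz + tag$heavy_addition
  imbalance <- exp(stats::rnorm(k, 0, spec$intensity_log_sd))
  data.frame(
    peak_id = c(paste0(ids, "_L"), paste0(ids, "_H")),
    mz = c(.jitter_mz(light_true, spec$mz_jitter_ppm),
           .jitter_mz(heavy_true, spec$mz_jitter_ppm)),
    rt = c(rt + stats::rnorm(k, 0, spec$rt_jitter_min),
           rt + stats::rnorm(k, 0, spec$rt_jitter_min)),
    intensity = c(base_int, base_int * imbalance) * attenuation,
    stringsAsFactors = FALSE)
}

# Untagged background features, optionally with isotope-envelope satellites.
.emit_background <- function(prefix, n, spec) {
  if (n == 0L) {
    return(data.frame(peak_id = character(), mz = numeric(), rt = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  }
  mz0 <- stats::runif(n, spec$mz_range[1], spec$mz_range[2])
  rt0 <- stats::runif(n, spec$rt_range[1], spec$rt_range[2])
  i0 <- stats::rlnorm(n, meanlog = log(1e5), sdlog = 1)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  out <- data.frame(peak_id = ids, mz = mz0, rt = rt0, intensity = i0,
                    stringsAsFactors = FALSE)
  if (spec$envelope_decoys) {
    rel <- cbind(stats::runif(n, 0.20, 0.35),
                 stats::runif(n, 0.03, 0.08),
                 stats::runif(n, 0.005, 0.015))
    sat <- do.call(rbind, lapply(1:3, function(k) data.frame(
      peak_id = paste0(ids, "_M", k),
      mz = .jitter_mz(mz0 + k * .C13_SPACING, spec$mz_jitter_ppm),
      rt = rt0 + stats::rnorm(n, 0, spec$rt_jitter_min),
      intensity = i0 * rel[, k],
      stringsAsFactors = FALSE)))
    out <- rbind(out, sat)
  }
  out
}

#' Generate pre/post feature tables with ground truth
#'
#' The pre table holds, per tagged compound, a light peak at
#' `parent + light_addition` and a heavy peak at `parent + heavy_addition`,
#' co-eluting within the RT jitter and with near-1:1 intensities, plus
#' untagged background (with isotope-envelope satellites when enabled). The
#' post table keeps the binder subset of compounds (attenuated, re-measured
#' with fresh noise) plus fresh cell background and the metabolite-only
#' pairs. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param tag A [tag_definition()]; default [propanoyl_tag()].
#' @return List with elements `pre` and `post` ([peak_table()]s) and
#'   `truth`, a data.frame with one row per compound: `compound_id`,
#'   `parent_mz`, `rt`, `n_tags`, `binder`, `metabolite_only`, `light_id`,
#'   `heavy_id`.
#' @export
generate_extract_tables <- function(spec = synthetic_spec(),
                                    tag = propanoyl_tag()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(tag, "tag_definition"))
  .with_seed(spec$seed, {
    nt <- spec$n_tagged_compounds
    # leave headroom so the tagged m/z stays inside a plausible scan range
    parent_mz <- stats::runif(nt, spec$mz_range[1], spec$mz_range[2])
    rt <- stats::runif(nt, spec$rt_range[1], spec$rt_range[2])
    base_int <- stats::rlnorm(nt, meanlog = log(1e5), sdlog = 1)
    ids <- sprintf("cmpd%04d", seq_len(nt))
    n_binders <- round(nt * spec$binder_fraction)
    binder <- rep(FALSE, nt)
    if (n_binders > 0) binder[sample.int(nt, n_binders)] <- TRUE

    pre_tagged <- .emit_pairs(ids, parent_mz, rt, base_int, spec, tag)
    pre_bg <- .emit_background("bg", spec$n_background, spec)
    pre <- peak_table(rbind(pre_tagged, pre_bg),
                      sample_label = "synthetic_extract",
                      role = "pre_binding",
                      provenance = list(generator = "isopair",
                                        seed = spec$seed))

    # metabolite-only compounds: tagged pairs that appear only post
    nm <- spec$n_metabolite_only
    met_ids <- if (nm > 0) sprintf("met%04d", seq_len(nm)) else character()
    met_parent <- stats::runif(nm, spec$mz_range[1], spec$mz_range[2])
    met_rt <- stats::runif(nm, spec$rt_range[1], spec$rt_range[2])
    met_int <- stats::rlnorm(nm, meanlog = log(1e4), sdlog = 1)

    post_tagged <- .emit_pairs(ids[binder], parent_mz[binder], rt[binder],
                               base_int[binder], spec, tag,
                               attenuation = spec$post_attenuation)
    post_met <- .emit_pairs(met_ids, met_parent, met_rt, met_int, spec, tag)
    post_bg <- .emit_background("cell", spec$n_background, spec)
    post <- peak_table(rbind(post_tagged, post_met, post_bg),
                       sample_label = "synthetic_lysate",
                       role = "post_binding",
                       provenance = list(generator = "isopair",
                                         seed = spec$seed))

    truth <- data.frame(
      compound_id = c(ids, met_ids),
      parent_mz = c(parent_mz, met_parent),
      rt = c(rt, met_rt),
      n_tags = 1L,
      binder = c(binder, rep(TRUE, nm)),
      metabolite_only = c(rep(FALSE, nt), rep(TRUE, nm)),
      light_id = paste0(c(ids, met_ids), "_L"),
      heavy_id = paste0(c(ids, met_ids), "_H"),
      stringsAsFactors = FALSE)

    list(pre = pre, post = post, truth = truth)
  })
}

#' Score a hit table against the generator's ground truth
#'
#' A hit is a true positive when its `(light_id, heavy_id)` pair belongs to
#' a ground-truth compound expected in the evaluated table (all
#' non-metabolite-only compounds for a pre-binding table; binders and
#' metabolite-only compounds for a post-binding table). Any other hit is a
#' false positive; expected pairs never reported are false negatives.
#'
#' @param hits A [hit_table()] produced from a synthetic table.
#' @param truth Ground-truth data.frame from [generate_extract_tables()].
#' @param role Which table the hits came from; defaults to the hit table's
#'   own role, treating `"other"` as pre-binding.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_detection <- function(hits, truth, role = NULL) {
  stopifnot(inherits(hits, "hit_table"), is.data.frame(truth))
  role <- role %||% hits$role
  expected <- if (identical(role, "post_binding"))
    truth[truth$binder | truth$metabolite_only, ] else
    truth[!truth$metabolite_only, ]
  truth_key <- paste(expected$light_id, expected$heavy_id, sep = "\r")
  hit_key <- unique(paste(hits$hits$light_id, hits$hits$heavy_id, sep = "\r"))
  tp <- sum(hit_key %in% truth_key)
  fp <- length(hit_key) - tp
  fn <- length(truth_key) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}
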