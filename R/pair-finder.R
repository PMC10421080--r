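# Detection of light/heavy isotopologue pairs within one feature table.
#
# The shifted-table method: every peak is a candidate light (12C-tag) member;
# its hypothetical heavy partner sits exactly n * pair_delta / z higher in
# m/z. Real peaks within the ppm window around that hypothetical m/z that
# also co-elute and have near-1:1 intensity are reported as pairs. The join
# runs on the m/z-sorted table with a binary-searched window per candidate
# (O(n log n + hits)); an exhaustive all-pairs oracle is provided for tests.

#' Tolerances for isotopologue-pair detection
#'
#' Defaults follow the tag-screening protocol: +/-3 ppm on the heavy-member
#' m/z against its expected position, +/-0.05 min co-elution, and at most a
#' 33% relative intensity difference between the twin peaks (the 1:1
#' light/heavy tagging makes larger imbalances implausible, and endogenous
#' M+3 isotope satellites fail this filter by an order of magnitude).
#'
#' @param mz_ppm Half-width ppm tolerance on m/z (> 0).
#' @param rt_window Half-width retention-time tolerance in minutes (> 0).
#' @param intensity_max_rel_diff Maximum allowed `|I_l - I_h| / max(I_l,
#'   I_h)`, in (0, 1].
#' @param n_tags Integer vector of tag multiplicities to search (default 1).
#' @param charge Assumed charge state (default 1).
#' @return Object of class `tolerance_policy`.
#' @export
tolerance_policy <- function(mz_ppm = 3, rt_window = 0.05,
                             intensity_max_rel_diff = 0.33,
                             n_tags = 1L, charge = 1L) {
  if (mz_ppm <= 0 || rt_window <= 0)
    stop("mz_ppm and rt_window must be positive")
  if (intensity_max_rel_diff <= 0 || intensity_max_rel_diff > 1)
    stop("intensity_max_rel_diff must lie in (0, 1]")
  n_tags <- sort(unique(as.integer(n_tags)))
  if (any(is.na(n_tags)) || any(n_tags < 1L))
    stop("n_tags must be positive integers")
  .check_charge(charge)
  structure(list(mz_ppm = mz_ppm, rt_window = rt_window,
                 intensity_max_rel_diff = intensity_max_rel_diff,
                 n_tags = n_tags, charge = as.integer(charge)),
            class = "tolerance_policy")
}

#' Relative intensity difference of two peaks
#'
#' Symmetric in its arguments and bounded in \[0, 1\]:
#' `|a - b| / max(a, b)` (0 when both intensities are 0).
#'
#' @param a,b Non-negative intensities (vectorized).
#' @return Fraction in \[0, 1\].
#' @export
intensity_rel_diff <- function(a, b) {
  m <- pmax(a, b)
  d <- abs(a - b)
  ifelse(m == 0, 0, d / m)
}

#' Find light/heavy isotopologue pairs in a feature table
#'
#' For each peak `p` (candidate light member) and each tag multiplicity `n`
#' in `policy$n_tags`, the expected heavy m/z is
#' `p$mz + n * tag$pair_delta / charge`. Every peak `q` satisfying all of
#' * `|ppm_error(q$mz, expected)| <= mz_ppm`,
#' * `|q$rt - p$rt| <= rt_window`,
#' * `intensity_rel_diff(p, q) <= intensity_max_rel_diff`
#' yields one hit. All qualifying pairs are reported; use
#' [deduplicate_hits()] to resolve lights matching several heavies. The hit
#' set is independent of the input row order.
#'
#' @param table A [peak_table()].
#' @param tag A [tag_definition()].
#' @param policy A [tolerance_policy()].
#' @return A [hit_table()]; empty input gives an empty hit table.
#' @seealso [brute_force_pairs()] for the exhaustive reference
#'   implementation used in tests.
#' @export
find_labeled_pairs <- function(table, tag = propanoyl_tag(),
                               policy = tolerance_policy()) {
  stopifnot(inherits(table, "peak_table"),
            inherits(tag, "tag_definition"),
            inherits(policy, "tolerance_policy"))
  if (any(policy$n_tags > tag$max_tags_per_compound))
    stop("policy searches more tags than max_tags_per_compound allows")
  p <- table$peaks
  if (nrow(p) < 2L)
    return(hit_table(sample_label = table$sample_label, role = table$role,
                     policy = policy))

  ord <- order(p$mz, p$peak_id)
  p <- p[ord, ]
  pieces <- vector("list", length(policy$n_tags))
  for (k in seq_along(policy$n_tags)) {
    n <- policy$n_tags[k]
    delta <- n * tag$pair_delta / policy$charge
    expected <- p$mz + delta
    lo <- expected * (1 - policy$mz_ppm * 1e-6)
    hi <- expected * (1 + policy$mz_ppm * 1e-6)
    first <- findInterval(lo, p$mz, left.open = TRUE) + 1L
    last <- findInterval(hi, p$mz)
    cnt <- pmax(last - first + 1L, 0L)
    if (sum(cnt) == 0L) next
    li <- rep.int(seq_len(nrow(p)), cnt)
    hv <- sequence(cnt) + rep.int(first - 1L, cnt)
    pieces[[k]] <- .assemble_hits(p, li, hv, n, expected[li], policy, tag)
  }
  hits <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(hits)) hits <- .empty_hits()
  hits <- hits[order(hits$light_id, hits$heavy_id, hits$n_tags), ,
               drop = FALSE]
  hit_table(hits, sample_label = table$sample_label, role = table$role,
            policy = policy)
}

# Evaluate the exact filters on candidate (light, heavy) index pairs and
# build hit rows. `expected` is the hypothetical heavy m/z per candidate.
.assemble_hits <- function(p, li, hv, n, expected, policy, tag) {
  ppm <- ppm_error(p$mz[hv], expected)
  rtd <- p$rt[hv] - p$rt[li]
  ird <- intensity_rel_diff(p$intensity[li], p$intensity[hv])
  keep <- li != hv &
    abs(ppm) <= policy$mz_ppm &
    abs(rtd) <= policy$rt_window &
    ird <= policy$intensity_max_rel_diff &
    p$mz[hv] > p$mz[li]
  if (!any(keep)) return(NULL)
  li <- li[keep]; hv <- hv[keep]
  data.frame(
    light_id = p$peak_id[li], heavy_id = p$peak_id[hv],
    light_mz = p$mz[li], heavy_mz = p$mz[hv],
    light_rt = p$rt[li], heavy_rt = p$rt[hv],
    light_intensity = p$intensity[li], heavy_intensity = p$intensity[hv],
    n_tags = n, ppm_error = ppm[keep], rt_delta = rtd[keep],
    intensity_rel_diff = ird[keep],
    inferred_parent_mz = p$mz[li] - n * tag$light_addition / policy$charge,
    stringsAsFactors = FALSE)
}

#' Exhaustive all-pairs isotopologue search (testing oracle)
#'
#' Same contract as [find_labeled_pairs()], implemented by evaluating every
#' ordered peak pair directly. Quadratic in the table size; intended for
#' small tables (a few thousand peaks) in tests and cross-checks.
#'
#' @inheritParams find_labeled_pairs
#' @return A [hit_table()].
#' @export
brute_force_pairs <- function(table, tag = propanoyl_tag(),
                              policy = tolerance_policy()) {
  stopifnot(inherits(table, "peak_table"),
            inherits(tag, "tag_definition"),
            inherits(policy, "tolerance_policy"))
  if (any(policy$n_tags > tag$max_tags_per_compound))
    stop("policy searches more tags than max_tags_per_compound allows")
  p <- table$peaks
  np <- nrow(p)
  if (np < 2L)
    return(hit_table(sample_label = table$sample_label, role = table$role,
                     policy = policy))
  idx <- expand.grid(li = seq_len(np), hv = seq_len(np))
  idx <- idx[idx$li != idx$hv, ]
  pieces <- lapply(policy$n_tags, function(n) {
    expected <- p$mz[idx$li] + n * tag$pair_delta / policy$charge
    .assemble_hits(p, idx$li, idx$hv, n, expected, policy, tag)
  })
  hits <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(hits)) hits <- .empty_hits()
  hits <- hits[order(hits$light_id, hits$heavy_id, hits$n_tags), ,
               drop = FALSE]
  hit_table(hits, sample_label = table$sample_label, role = table$role,
            policy = policy)
}

#' Resolve light peaks matching several heavy peaks
#'
#' @param table A [hit_table()].
#' @param strategy `"keep_all"` returns the input unchanged; `"best_ppm"`
#'   keeps, for each light peak, the hit with the smallest `|ppm_error|`
#'   (ties broken by smaller `|rt_delta|`, then smaller heavy m/z).
#' @return A [hit_table()].
#' @export
deduplicate_hits <- function(table, strategy = c("keep_all", "best_ppm")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(table, "hit_table"))
  if (strategy == "keep_all" || nrow(table$hits) == 0L) return(table)
  h <- table$hits
  h <- h[order(h$light_id, abs(h$ppm_error), abs(h$rt_delta), h$heavy_mz), ]
  h <- h[!duplicated(h$light_id), ]
  h <- h[order(h$light_id, h$heavy_id, h$n_tags), ]
  hit_table(h, sample_label = table$sample_label, role = table$role,
            policy = table$policy)
}
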