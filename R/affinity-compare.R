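# Cross-referencing pre-incubation and post-cell-affinity hit tables.
#
# A pair detected in the tagged extract (pre) that is re-detected in the
# cell lysate (post) within the cross-sample tolerances is an enriched hit:
# the compound bound tightly enough to survive the washes. Pairs present
# only post suggest cellular metabolism of a tagged parent. The cross-sample
# tolerances are deliberately looser than pair detection (+/-4 ppm, +/-0.5
# min): the two tables come from separate injections, so retention drifts.

#' Tolerances for pre/post hit-table matching
#'
#' @param mz_ppm Half-width ppm tolerance on the light-member m/z
#'   (default 4). Evaluated against the mean of the two compared m/z values
#'   so the relation is symmetric.
#' @param rt_window Half-width retention-time tolerance in minutes
#'   (default 0.5).
#' @return Object of class `match_policy`.
#' @export
match_policy <- function(mz_ppm = 4, rt_window = 0.5) {
  if (mz_ppm <= 0 || rt_window <= 0)
    stop("mz_ppm and rt_window must be positive")
  structure(list(mz_ppm = mz_ppm, rt_window = rt_window),
            class = "match_policy")
}

#' Match hit tables recorded before and after the cell-affinity assay
#'
#' Two hits match when their light-member m/z values agree within
#' `policy$mz_ppm` (ppm computed against the mean of the two m/z values) and
#' their light-member retention times agree within `policy$rt_window`.
#' Matching is a one-to-one greedy assignment: candidate pairs are taken in
#' order of increasing ppm difference (ties by RT difference), and each pre
#' hit claims at most one post hit. The result partitions both tables:
#' every pre hit is either matched or pre-only, every post hit matched or
#' post-only.
#'
#' @param pre Hit table of the tagged extract before incubation.
#' @param post Hit table of the cell lysate after incubation and washing.
#' @param policy A [match_policy()].
#' @return Object of class `enrichment_report`: list with `matched`
#'   (data.frame of paired pre/post hits, prefixed columns), `pre_only` and
#'   `post_only` (hit data.frames), `enrichment_fraction`, `counts`, and the
#'   `policy`.
#' @export
match_hit_tables <- function(pre, post, policy = match_policy()) {
  stopifnot(inherits(pre, "hit_table"), inherits(post, "hit_table"),
            inherits(policy, "match_policy"))
  hpre <- pre$hits
  hpost <- post$hits
  npre <- nrow(hpre)
  npost <- nrow(hpost)

  assign_pre <- rep(NA_integer_, npre)
  assign_post <- rep(NA_integer_, npost)
  if (npre > 0L && npost > 0L) {
    cand <- expand.grid(i = seq_len(npre), j = seq_len(npost))
    mz_i <- hpre$light_mz[cand$i]
    mz_j <- hpost$light_mz[cand$j]
    ppm <- 1e6 * abs(mz_i - mz_j) / ((mz_i + mz_j) / 2)
    rtd <- abs(hpre$light_rt[cand$i] - hpost$light_rt[cand$j])
    ok <- ppm <= policy$mz_ppm & rtd <= policy$rt_window
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      o <- order(ppm[ok], rtd[ok], cand$i, cand$j)
      cand <- cand[o, , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (is.na(assign_pre[i]) && is.na(assign_post[j])) {
          assign_pre[i] <- j
          assign_post[j] <- i
        }
      }
    }
  }

  mi <- which(!is.na(assign_pre))
  matched <- if (length(mi)) {
    a <- hpre[mi, , drop = FALSE]
    b <- hpost[assign_pre[mi], , drop = FALSE]
    names(a) <- paste0("pre_", names(a))
    names(b) <- paste0("post_", names(b))
    rownames(a) <- rownames(b) <- NULL
    cbind(a, b)
  } else {
    a <- .empty_hits(); b <- .empty_hits()
    names(a) <- paste0("pre_", names(a))
    names(b) <- paste0("post_", names(b))
    cbind(a, b)
  }
  pre_only <- hpre[is.na(assign_pre), , drop = FALSE]
  post_only <- hpost[is.na(assign_post), , drop = FALSE]
  rownames(pre_only) <- rownames(post_only) <- NULL

  structure(list(
    matched = matched,
    pre_only = pre_only,
    post_only = post_only,
    enrichment_fraction = if (npre > 0L) length(mi) / npre else 0,
    counts = c(pre = npre, post = npost, matched = length(mi),
               pre_only = nrow(pre_only), post_only = nrow(post_only)),
    policy = policy,
    pre_label = pre$sample_label,
    post_label = post$sample_label
  ), class = "enrichment_report")
}

#' Fraction of extract hits enriched by the cell-affinity assay
#'
#' The number of matched (pre and post) hits divided by the number of pre
#' hits; 0 by convention when the pre table is empty. In tag-screening runs
#' of crude plant extracts this fraction typically lands in the few-percent
#' range.
#'
#' @param report An `enrichment_report` from [match_hit_tables()].
#' @return Fraction in \[0, 1\].
#' @export
enrichment_fraction <- function(report) {
  stopifnot(inherits(report, "enrichment_report"))
  report$enrichment_fraction
}

#' Hits present only after the cell-affinity assay
#'
#' Pairs detected in the lysate but absent from the extract are candidate
#' metabolized or cell-derived tagged compounds.
#'
#' @param report An `enrichment_report` from [match_hit_tables()].
#' @return A [hit_table()] (role `"post_binding"`).
#' @export
post_only_hits <- function(report) {
  stopifnot(inherits(report, "enrichment_report"))
  hit_table(report$post_only, sample_label = report$post_label,
            role = "post_binding")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>\n")
  cat(sprintf("  pre hits:  %d   post hits: %d\n",
              x$counts[["pre"]], x$counts[["post"]]))
  cat(sprintf("  matched:   %d   pre-only: %d   post-only: %d\n",
              x$counts[["matched"]], x$counts[["pre_only"]],
              x$counts[["post_only"]]))
  cat(sprintf("  enrichment fraction: %.3f\n", x$enrichment_fraction))
  invisible(x)
}
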