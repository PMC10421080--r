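# The hit table: detected light/heavy isotopologue pairs for one sample.

.HIT_COLUMNS <- c("light_id", "heavy_id", "light_mz", "heavy_mz",
                  "light_rt", "heavy_rt", "light_intensity",
                  "heavy_intensity", "n_tags", "ppm_error", "rt_delta",
                  "intensity_rel_diff", "inferred_parent_mz")

.empty_hits <- function() {
  df <- data.frame(light_id = character(), heavy_id = character(),
                   light_mz = numeric(), heavy_mz = numeric(),
                   light_rt = numeric(), heavy_rt = numeric(),
                   light_intensity = numeric(), heavy_intensity = numeric(),
                   n_tags = integer(), ppm_error = numeric(),
                   rt_delta = numeric(), intensity_rel_diff = numeric(),
                   inferred_parent_mz = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Construct a hit table
#'
#' A hit table collects the detected isotopologue pairs of one sample: for
#' every pair, the m/z, retention time and intensity of both member peaks,
#' the quality metrics of the match, and the inferred untagged parent m/z.
#'
#' @param hits data.frame with columns `light_id`, `heavy_id`, `light_mz`,
#'   `heavy_mz`, `light_rt`, `heavy_rt`, `light_intensity`,
#'   `heavy_intensity`, `n_tags`, `ppm_error`, `rt_delta`,
#'   `intensity_rel_diff`, `inferred_parent_mz`.
#' @param sample_label Sample name.
#' @param role Table role (`"pre_binding"`, `"post_binding"`, `"other"`).
#' @param policy The [tolerance_policy()] the hits satisfy, or `NULL`.
#' @return Object of class `hit_table`.
#' @export
hit_table <- function(hits = .empty_hits(), sample_label = "",
                      role = c("other", "pre_binding", "post_binding"),
                      policy = NULL) {
  role <- match.arg(role)
  stopifnot(is.data.frame(hits))
  missing_cols <- setdiff(.HIT_COLUMNS, names(hits))
  if (length(missing_cols))
    stop("hit table lacks column(s): ", paste(missing_cols, collapse = ", "))
  hits <- hits[, .HIT_COLUMNS]
  hits$light_id <- as.character(hits$light_id)
  hits$heavy_id <- as.character(hits$heavy_id)
  hits$n_tags <- as.integer(hits$n_tags)
  if (anyDuplicated(hits[, c("light_id", "heavy_id", "n_tags")]))
    stop("duplicated (light_id, heavy_id, n_tags) hit")
  rownames(hits) <- NULL
  structure(list(sample_label = sample_label, role = role,
                 policy = policy, hits = hits),
            class = "hit_table")
}

#' Number of hits in a hit table
#' @param table A [hit_table()].
#' @return Integer count.
#' @export
n_hits <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  nrow(table$hits)
}

#' @export
as.data.frame.hit_table <- function(x, ...) x$hits

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %s (%s): %d isotopologue pair(s)\n",
              x$sample_label, x$role, nrow(x$hits)))
  if (!is.null(x$policy))
    cat(sprintf("  policy: +/-%g ppm, +/-%g min, <=%.0f%% intensity diff\n",
                x$policy$mz_ppm, x$policy$rt_window,
                100 * x$policy$intensity_max_rel_diff))
  invisible(x)
}

#' Write a hit table to CSV
#'
#' One row per detected pair, carrying both member peaks (m/z, RT,
#' intensity), the match metrics, the tag count and the inferred untagged
#' parent m/z. [read_hit_table()] restores the hit set losslessly.
#'
#' @param table A [hit_table()].
#' @param path Destination CSV file.
#' @return The path, invisibly.
#' @export
write_hit_table <- function(table, path) {
  stopifnot(inherits(table, "hit_table"))
  .write_csv(table$hits, path)
}

#' Read a hit table written by [write_hit_table()]
#'
#' @param path CSV file path.
#' @param sample_label,role As in [hit_table()]; defaults taken from the
#'   file name.
#' @return A [hit_table()] (its policy field is `NULL`; the tolerances used
#'   to produce the hits are not stored in the CSV).
#' @export
read_hit_table <- function(path, sample_label = basename(path),
                           role = c("other", "pre_binding", "post_binding")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("hit table file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = c(light_id = "character",
                                       heavy_id = "character"))
  if (nrow(df) == 0L && ncol(df) == length(.HIT_COLUMNS)) df <- .empty_hits()
  hit_table(df, sample_label = sample_label, role = role)
}
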