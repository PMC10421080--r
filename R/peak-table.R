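# Reading and writing aligned LC-MS feature tables.
#
# A peak table is whatever the upstream peak picker (MS-DIAL or similar)
# exported: one row per aligned feature with m/z, retention time (minutes)
# and an abundance value. Two CSV dialects are supported out of the box plus
# a user-supplied column map; invalid rows are dropped and counted rather
# than aborting the load, because real exports carry blank and footer rows.

.DIALECTS <- list(
  generic = list(mz = "mz", rt = "rt", intensity = "intensity", id = "peak_id"),
  # MS-DIAL alignment-export headers; versions vary, hence overridable.
  msdial = list(mz = "Average Mz", rt = "Average Rt(min)",
                intensity = "Height", id = "Alignment ID")
)

#' Construct a peak table
#'
#' @param peaks data.frame with numeric columns `mz`, `rt`, `intensity` and
#'   optionally `peak_id` (generated as `"p<row>"` when absent). `mz` must be
#'   positive, `rt` and `intensity` non-negative, ids unique.
#' @param sample_label Free-text sample name.
#' @param role One of `"pre_binding"` (tagged extract before the cell
#'   assay), `"post_binding"` (cell-lysate sample) or `"other"`.
#' @param provenance Optional list recording source path/dialect.
#' @return Object of class `peak_table`: a list with fields `sample_label`,
#'   `role`, `peaks` (data.frame) and `provenance`.
#' @export
peak_table <- function(peaks, sample_label = "",
                       role = c("other", "pre_binding", "post_binding"),
                       provenance = list()) {
  role <- match.arg(role)
  stopifnot(is.data.frame(peaks))
  required <- c("mz", "rt", "intensity")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols))
    stop("peak table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"peak_id" %in% names(peaks))
    peaks$peak_id <- if (nrow(peaks)) paste0("p", seq_len(nrow(peaks))) else character()
  peaks$peak_id <- as.character(peaks$peak_id)
  if (anyDuplicated(peaks$peak_id)) stop("peak_id values must be unique")
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("all m/z values must be positive")
    if (any(peaks$rt < 0)) stop("retention times must be non-negative")
    if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
  }
  peaks <- peaks[, c("peak_id", required)]
  rownames(peaks) <- NULL
  structure(list(sample_label = sample_label, role = role,
                 peaks = peaks, provenance = provenance),
            class = "peak_table")
}

#' Read an aligned feature table from CSV
#'
#' Maps columns according to the chosen dialect (or an explicit
#' `column_map`), coerces them to numeric, and drops rows whose m/z, RT or
#' intensity is missing, non-numeric or out of range (m/z <= 0, RT < 0,
#' intensity < 0). Dropped rows are counted in the load report attached to
#' the result (see [load_report()]). Retention times are taken to be in
#' minutes.
#'
#' @param path CSV file path.
#' @param dialect `"generic"` (columns `mz`, `rt`, `intensity`, optional
#'   `peak_id`), `"msdial"` (MS-DIAL alignment-export headers) or
#'   `"custom"` with `column_map` supplied.
#' @param column_map Named list with entries `mz`, `rt`, `intensity` and
#'   optionally `id`, giving the header names to use; overrides the dialect
#'   map.
#' @param sample_label Sample name; defaults to the file name.
#' @param role Table role, as in [peak_table()].
#' @return A [peak_table()] with a `"load_report"` attribute. An empty table
#'   (no valid rows) is returned as a zero-row `peak_table`, not an error.
#' @export
read_peak_table <- function(path, dialect = c("generic", "msdial", "custom"),
                            column_map = NULL, sample_label = basename(path),
                            role = c("other", "pre_binding", "post_binding")) {
  dialect <- match.arg(dialect)
  role <- match.arg(role)
  if (!file.exists(path)) stop("peak table file not found: ", path)
  map <- if (dialect == "custom") {
    if (is.null(column_map))
      stop("dialect 'custom' requires a column_map with mz, rt, intensity")
    column_map
  } else utils::modifyList(.DIALECTS[[dialect]], as.list(column_map))
  for (f in c("mz", "rt", "intensity"))
    if (is.null(map[[f]])) stop("column_map lacks an entry for '", f, "'")

  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(map[c("mz", "rt", "intensity")]), names(raw))
  if (length(missing_cols))
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))

  num <- function(x) suppressWarnings(as.numeric(x))
  peaks <- data.frame(mz = num(raw[[map$mz]]),
                      rt = num(raw[[map$rt]]),
                      intensity = num(raw[[map$intensity]]))
  if (!is.null(map$id) && map$id %in% names(raw))
    peaks$peak_id <- as.character(raw[[map$id]])

  ok <- !is.na(peaks$mz) & !is.na(peaks$rt) & !is.na(peaks$intensity) &
    peaks$mz > 0 & peaks$rt >= 0 & peaks$intensity >= 0
  dropped <- sum(!ok)
  peaks <- peaks[ok, , drop = FALSE]
  rownames(peaks) <- NULL
  if ("peak_id" %in% names(peaks) && anyDuplicated(peaks$peak_id))
    peaks$peak_id <- NULL  # fall back to row ids rather than fail the load

  pt <- peak_table(peaks, sample_label = sample_label, role = role,
                   provenance = list(path = path, dialect = dialect,
                                     rows_in_file = nrow(raw)))
  attr(pt, "load_report") <- list(path = path, dialect = dialect,
                                  n_read = nrow(raw),
                                  n_kept = nrow(peaks),
                                  n_dropped = dropped)
  if (nrow(peaks) == 0L)
    warning("no valid peaks in ", path, " (", nrow(raw), " rows read)")
  pt
}

#' Load report of a peak table read from file
#'
#' @param table A [peak_table()] produced by [read_peak_table()].
#' @return List with `path`, `dialect`, `n_read`, `n_kept`, `n_dropped`, or
#'   `NULL` for tables not read from a file.
#' @export
load_report <- function(table) attr(table, "load_report")

#' Write a peak table to CSV
#'
#' @param table A [peak_table()].
#' @param path Destination file.
#' @param dialect Output dialect, `"generic"` or `"msdial"`; headers follow
#'   the same maps used by [read_peak_table()].
#' @return The path, invisibly.
#' @export
write_peak_table <- function(table, path, dialect = c("generic", "msdial")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "peak_table"))
  map <- .DIALECTS[[dialect]]
  out <- table$peaks[, c("peak_id", "mz", "rt", "intensity")]
  names(out) <- c(map$id, map$mz, map$rt, map$intensity)
  .write_csv(out, path)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %s (%s): %d peaks\n",
              x$sample_label, x$role, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat(sprintf("  m/z %.4f-%.4f, RT %.2f-%.2f min\n",
                min(x$peaks$mz), max(x$peaks$mz),
                min(x$peaks$rt), max(x$peaks$rt)))
  }
  invisible(x)
}

.write_csv <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("failed to write ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
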