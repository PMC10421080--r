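# Mass arithmetic relating observed m/z, tag additions and parent ions.
# All functions are vectorized over their m/z argument and compute at full
# double precision; rounding to 4 decimals is a display convention only.

#' m/z separation of a light/heavy isotopologue pair
#'
#' The twin peaks of a compound carrying `n_tags` tags are separated by
#' `n_tags * pair_delta / charge` on the m/z axis. For the default propanoyl
#' tag at charge 1 and one tag this is 3.010065, the +3.0101 spacing used to
#' build the shifted hypothetical peak table.
#'
#' @param n_tags Non-negative integer tag count(s).
#' @param charge Positive integer charge (default 1).
#' @param tag A [tag_definition()]; default [propanoyl_tag()].
#' @return m/z delta(s), heavy minus light.
#' @examples
#' round(tag_delta_mz(1), 4)  # 3.0101
#' @export
tag_delta_mz <- function(n_tags, charge = 1L, tag = propanoyl_tag()) {
  stopifnot(inherits(tag, "tag_definition"))
  if (any(n_tags < 0)) stop("n_tags must be non-negative")
  .check_charge(charge)
  n_tags * tag$pair_delta / charge
}

#' m/z of a tagged ion from its untagged parent ion
#'
#' Adds `n_tags` light or heavy tag additions (divided by charge) to the
#' parent ion m/z.
#'
#' @param parent_mz Untagged parent ion m/z (> 0).
#' @param n_tags Positive integer number of tags.
#' @param variant `"light"` or `"heavy"`.
#' @param tag A [tag_definition()].
#' @param charge Positive integer charge.
#' @return Tagged ion m/z.
#' @examples
#' round(tagged_mz(975.5297, 1, "light"), 4)  # 1031.5559
#' @export
tagged_mz <- function(parent_mz, n_tags = 1L, variant = c("light", "heavy"),
                      tag = propanoyl_tag(), charge = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(tag, "tag_definition"))
  if (any(parent_mz <= 0)) stop("parent_mz must be positive")
  .check_n_tags(n_tags, tag)
  .check_charge(charge)
  add <- if (variant == "light") tag$light_addition else tag$heavy_addition
  parent_mz + n_tags * add / charge
}

#' Untagged parent ion m/z from a tagged ion
#'
#' Exact inverse of [tagged_mz()]: subtracts `n_tags` tag additions (divided
#' by charge) from the observed tagged m/z.
#'
#' @param mz Tagged ion m/z.
#' @inheritParams tagged_mz
#' @return Parent ion m/z; an error if the subtraction is non-positive.
#' @examples
#' round(parent_mz_from_tagged(1031.5559, 1, "light"), 4)  # 975.5297
#' @export
parent_mz_from_tagged <- function(mz, n_tags = 1L,
                                  variant = c("light", "heavy"),
                                  tag = propanoyl_tag(), charge = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(tag, "tag_definition"))
  .check_n_tags(n_tags, tag)
  .check_charge(charge)
  add <- if (variant == "light") tag$light_addition else tag$heavy_addition
  out <- mz - n_tags * add / charge
  if (any(out <= 0))
    stop("subtracting ", n_tags, " tag addition(s) leaves a non-positive m/z")
  out
}

#' Neutral (or intrinsic-cation) mass from an observed m/z
#'
#' Subtracts the adduct mass shift under the charge-1 convention. The adduct
#' `"none"` (intrinsic cations such as pyridinium alkaloids) returns the m/z
#' unchanged.
#'
#' @param mz Observed m/z.
#' @param adduct Adduct name; see [default_adducts()].
#' @param adducts Adduct lookup table.
#' @return Mass in Da.
#' @examples
#' neutral_mass(502.3313, "none")          # 502.3313 (intrinsic cation)
#' round(neutral_mass(538.2796, "NH4+"), 4)
#' @export
neutral_mass <- function(mz, adduct = "none", adducts = default_adducts()) {
  shift <- adduct_shift(adduct, adducts)
  if (any(mz <= shift)) stop("m/z must exceed the adduct mass shift")
  mz - shift
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param expected Expected m/z (> 0).
#' @return `1e6 * (observed - expected) / expected`.
#' @export
ppm_error <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected m/z must be positive")
  1e6 * (observed - expected) / expected
}

.check_charge <- function(charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  invisible(charge)
}

.check_n_tags <- function(n_tags, tag) {
  if (any(n_tags < 1) || any(n_tags != as.integer(n_tags)))
    stop("n_tags must be a positive integer")
  if (any(n_tags > tag$max_tags_per_compound))
    stop("n_tags exceeds max_tags_per_compound (",
         tag$max_tags_per_compound, ") for tag '", tag$name, "'")
  invisible(n_tags)
}
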