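# Monoisotopic mass constants and tag/adduct definitions.
#
# Masses are pinned to a fixed table (CODATA/AME values, >= 6 decimals) so
# that every m/z computed by the package is bit-identical across machines.

.ELEMENT_MASSES <- c(
  C12      = 12.0,
  C13      = 13.003354835,
  H1       = 1.007825032,
  N14      = 14.003074004,
  O16      = 15.994914620,
  Na23     = 22.989769282,
  S32      = 31.972071174,
  electron = 0.000548580
)

#' Monoisotopic element masses used by the package
#'
#' Returns the fixed table of monoisotopic masses (Da) the package computes
#' with: 12C, 13C, 1H, 14N, 16O, 23Na, 32S and the electron. The table is
#' pinned rather than looked up at run time so that mass arithmetic is
#' reproducible to the least significant digit.
#'
#' @return Named numeric vector of masses in Da.
#' @examples
#' element_masses()[["C13"]] - element_masses()[["C12"]]  # ~1.0033548
#' @export
element_masses <- function() .ELEMENT_MASSES

#' Monoisotopic mass of an elemental composition
#'
#' @param C,H,N,O,Na,S Non-negative atom counts (most abundant isotope).
#' @param C13 Count of heavy carbon atoms, for isotope-labeled compositions.
#' @return Mass in Da.
#' @examples
#' composition_mass(C = 3, H = 4, O = 1)  # net mass added by one propanoylation
#' @export
composition_mass <- function(C = 0, H = 0, N = 0, O = 0, Na = 0, S = 0, C13 = 0) {
  counts <- c(C, H, N, O, Na, S, C13)
  if (any(counts < 0)) stop("atom counts must be non-negative")
  m <- .ELEMENT_MASSES
  C * m[["C12"]] + H * m[["H1"]] + N * m[["N14"]] + O * m[["O16"]] +
    Na * m[["Na23"]] + S * m[["S32"]] + C13 * m[["C13"]]
}

#' Define an isotopic tag
#'
#' A tag is a derivatization applied as a 1:1 mixture of a light and a heavy
#' isotopologue of the same reagent, so that every tagged compound appears in
#' a feature table as a twin peak separated by `pair_delta` (at charge 1).
#'
#' @param name Tag name.
#' @param light_addition Net mass (Da) added to a compound by one light-tag
#'   acylation.
#' @param heavy_addition Net mass (Da) added by one heavy-tag acylation;
#'   must exceed `light_addition`.
#' @param max_tags_per_compound Largest tag multiplicity the mass arithmetic
#'   will accept.
#' @return Object of class `tag_definition` with fields `name`,
#'   `light_addition`, `heavy_addition`, `pair_delta`
#'   (`heavy_addition - light_addition`) and `max_tags_per_compound`.
#' @seealso [propanoyl_tag()] for the default 12C3/13C3-propanoyl tag.
#' @export
tag_definition <- function(name, light_addition, heavy_addition,
                           max_tags_per_compound = 3L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(light_addition), length(light_addition) == 1L,
            is.numeric(heavy_addition), length(heavy_addition) == 1L)
  if (light_addition <= 0) stop("light_addition must be positive")
  if (heavy_addition <= light_addition)
    stop("heavy_addition must exceed light_addition (pair_delta > 0)")
  max_tags_per_compound <- as.integer(max_tags_per_compound)
  if (is.na(max_tags_per_compound) || max_tags_per_compound < 1L)
    stop("max_tags_per_compound must be a positive integer")
  structure(
    list(name = name,
         light_addition = light_addition,
         heavy_addition = heavy_addition,
         pair_delta = heavy_addition - light_addition,
         max_tags_per_compound = max_tags_per_compound),
    class = "tag_definition")
}

#' The default 12C3/13C3-propanoyl tag
#'
#' One propanoylation of a hydroxyl or phenol adds the net composition C3H4O
#' (about 56.026215 Da). The heavy reagent carries three 13C atoms, so the
#' light/heavy pair delta is 3 x (m(13C) - m(12C)) = 3.010065 Da, which
#' rounds to the familiar +3.0101 m/z twin-peak spacing at charge 1.
#'
#' @param max_tags_per_compound Largest tag multiplicity accepted (default 3).
#' @return A [tag_definition()].
#' @examples
#' tag <- propanoyl_tag()
#' round(tag$pair_delta, 4)  # 3.0101
#' @export
propanoyl_tag <- function(max_tags_per_compound = 3L) {
  light <- composition_mass(C = 3, H = 4, O = 1)
  heavy <- composition_mass(H = 4, O = 1, C13 = 3)
  tag_definition("propanoyl", light, heavy, max_tags_per_compound)
}

# Cationic adduct shifts include the loss of one electron; "none" covers
# intrinsic cations (e.g. pyridinium alkaloids) observed without adduction.
.default_adduct_table <- function() {
  m <- .ELEMENT_MASSES
  e <- m[["electron"]]
  data.frame(
    name = c("H+", "Na+", "NH4+", "none"),
    mass_shift = c(m[["H1"]] - e,
                   m[["Na23"]] - e,
                   m[["N14"]] + 4 * m[["H1"]] - e,
                   0),
    charge = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Adduct table for neutral-mass arithmetic
#'
#' @return A data.frame with columns `name`, `mass_shift` (Da added to the
#'   neutral or intrinsic-cation mass to obtain the observed m/z at charge 1)
#'   and `charge`. Shifts for H+, Na+ and NH4+ account for electron loss.
#' @export
default_adducts <- function() .default_adduct_table()

#' Look up an adduct mass shift by name
#'
#' @param name Adduct name (`"H+"`, `"Na+"`, `"NH4+"`, `"none"`).
#' @param adducts Adduct table, default [default_adducts()].
#' @return Mass shift in Da.
#' @export
adduct_shift <- function(name, adducts = default_adducts()) {
  i <- match(name, adducts$name)
  if (anyNA(i))
    stop("unknown adduct: ", paste(name[is.na(i)], collapse = ", "),
         " (known: ", paste(adducts$name, collapse = ", "), ")")
  adducts$mass_shift[i]
}

#' Load tag and adduct definitions from a YAML configuration file
#'
#' The package ships its defaults in
#' `system.file("extdata", "tag_config.yaml", package = "isopair")`; a user
#' file with the same layout (a `tags` list with `name`, `light_addition`,
#' `heavy_addition`, `max_tags_per_compound`, and an `adducts` list with
#' `name`, `mass_shift`, `charge`) overrides them.
#'
#' @param path Path to a YAML file; default is the shipped configuration.
#' @return List with elements `tags` (named list of [tag_definition()]s) and
#'   `adducts` (data.frame as in [default_adducts()]).
#' @export
load_tag_config <- function(path = system.file("extdata", "tag_config.yaml",
                                               package = "isopair")) {
  if (!nzchar(path) || !file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tags)) stop("config has no 'tags' section: ", path)
  tags <- lapply(cfg$tags, function(t)
    tag_definition(t$name, t$light_addition, t$heavy_addition,
                   t$max_tags_per_compound %||% 3L))
  names(tags) <- vapply(tags, `[[`, "", "name")
  adducts <- if (is.null(cfg$adducts)) default_adducts() else
    data.frame(
      name = vapply(cfg$adducts, `[[`, "", "name"),
      mass_shift = vapply(cfg$adducts, function(a) as.numeric(a$mass_shift), 0),
      charge = vapply(cfg$adducts, function(a) as.integer(a$charge %||% 1L), 0L),
      stringsAsFactors = FALSE)
  list(tags = tags, adducts = adducts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tag_definition <- function(x, ...) {
  cat(sprintf("<tag_definition> %s\n", x$name))
  cat(sprintf("  light addition: %.6f Da\n", x$light_addition))
  cat(sprintf("  heavy addition: %.6f Da\n", x$heavy_addition))
  cat(sprintf("  pair delta:     %.6f Da (max %d tags/compound)\n",
              x$pair_delta, x$max_tags_per_compound))
  invisible(x)
}
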