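## Elemental and residue mass bookkeeping.
##
## All monoisotopic and average masses in the package are derived from one
## internal table of IUPAC isotope masses/abundances and standard atomic
## weights, so that peptide, glycan and proteoform masses are additive by
## construction.

# isotope masses (Da) and natural abundances per element; nominal-mass offsets
# relative to the lightest isotope
.elements <- list(
  C = list(mass = c(12.0000000, 13.0033548), ab = c(0.9893, 0.0107),
           offset = c(0L, 1L), average = 12.011),
  H = list(mass = c(1.0078250, 2.0141018), ab = c(0.999885, 0.000115),
           offset = c(0L, 1L), average = 1.008),
  N = list(mass = c(14.0030740, 15.0001089), ab = c(0.99636, 0.00364),
           offset = c(0L, 1L), average = 14.007),
  O = list(mass = c(15.9949146, 16.9991315, 17.9991604),
           ab = c(0.99757, 0.00038, 0.00205),
           offset = c(0L, 1L, 2L), average = 15.999),
  S = list(mass = c(31.9720707, 32.9714589, 33.9678669, 35.9670809),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001),
           offset = c(0L, 1L, 2L, 4L), average = 32.06)
)

.proton_mass <- 1.007276

# residue (dehydrated) elemental formulas, CHNOS
.aa_formula <- list(
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0)
)

# glycan residue (dehydrated) formulas
.glycan_formula <- list(
  hex    = c(C = 6, H = 10, N = 0, O = 5, S = 0),
  hexnac = c(C = 8, H = 13, N = 1, O = 5, S = 0),
  dhex   = c(C = 6, H = 10, N = 0, O = 4, S = 0),
  neuac  = c(C = 11, H = 17, N = 1, O = 8, S = 0)
)

.water    <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
.h2       <- c(C = 0, H = 2, N = 0, O = 0, S = 0)

# named fixed modifications: elemental deltas (may be negative)
.mod_delta <- list(
  carboxymethyl_cys = list(target = "C", delta = c(C = 2, H = 2, N = 0, O = 2, S = 0)),
  met_oxidation     = list(target = "M", delta = c(C = 0, H = 0, N = 0, O = 1, S = 0)),
  deamidation       = list(target = c("N", "Q"),
                           delta = c(C = 0, H = -1, N = -1, O = 1, S = 0))
)

.zero_comp <- c(C = 0, H = 0, N = 0, O = 0, S = 0)

#' Monoisotopic mass of an elemental composition
#' @param comp named integer vector with any of C, H, N, O, S
#' @return mass in Da
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_comp(comp)
  sum(vapply(names(comp), function(e) comp[[e]] * .elements[[e]]$mass[1],
             numeric(1)))
}

#' Average mass of an elemental composition
#' @inheritParams monoisotopic_mass
#' @return mass in Da
#' @export
average_mass <- function(comp) {
  comp <- .as_comp(comp)
  sum(vapply(names(comp), function(e) comp[[e]] * .elements[[e]]$average,
             numeric(1)))
}

.as_comp <- function(comp) {
  if (is.null(names(comp))) stop("composition must be a named vector")
  bad <- setdiff(names(comp), names(.zero_comp))
  if (length(bad)) stop("unsupported elements: ", paste(bad, collapse = ", "))
  if (any(comp < 0)) stop("negative element counts")
  out <- .zero_comp
  out[names(comp)] <- comp
  out
}

.mass_value <- function(comp) {
  structure(list(monoisotopic = monoisotopic_mass(comp),
                 average = average_mass(comp),
                 composition = .as_comp(comp)),
            class = "mass_value")
}

#' @export
print.mass_value <- function(x, ...) {
  cat(sprintf("mass: %.4f Da monoisotopic, %.2f Da average\n",
              x$monoisotopic, x$average))
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' @param sequence amino-acid string (20 standard one-letter codes)
#' @param fixed_mods character vector of modification names applied to every
#'   matching residue: `"carboxymethyl_cys"`, `"met_oxidation"`,
#'   `"deamidation"`
#' @return named CHNOS count vector
#' @export
peptide_composition <- function(sequence, fixed_mods = character()) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  unknown <- which(!aa %in% names(.aa_formula))
  if (length(unknown))
    stop(sprintf("unknown residue '%s' at position %d", aa[unknown[1]],
                 unknown[1]))
  comp <- Reduce(`+`, .aa_formula[aa]) + .water
  for (m in fixed_mods) {
    if (!m %in% names(.mod_delta)) stop("unknown modification: ", m)
    n_target <- sum(aa %in% .mod_delta[[m]]$target)
    comp <- comp + n_target * .mod_delta[[m]]$delta
  }
  if (any(comp < 0)) stop("modifications produced a negative element count")
  comp
}

#' Peptide mass (monoisotopic and average)
#'
#' Sum of residue masses plus one water; fixed modifications are applied to
#' every residue they target.
#'
#' @inheritParams peptide_composition
#' @return a `mass_value` with fields `monoisotopic`, `average`,
#'   `composition`
#' @examples
#' peptide_mass("IRTTMR")  # 776.4327 Da monoisotopic
#' @export
peptide_mass <- function(sequence, fixed_mods = character()) {
  .mass_value(peptide_composition(sequence, fixed_mods))
}

#' Elemental composition of a glycan
#'
#' @param composition named counts with any of `hex`, `hexnac`, `dhex`,
#'   `neuac`
#' @param form `"reduced-alditol"` (free, borohydride-reduced: + water + 2H)
#'   or `"bound"` (glycosidically bound residue sum, added to a carrier)
#' @return named CHNOS count vector
#' @export
glycan_composition <- function(composition,
                               form = c("reduced-alditol", "bound")) {
  form <- match.arg(form)
  bad <- setdiff(names(composition), names(.glycan_formula))
  if (length(bad)) stop("unknown monosaccharides: ", paste(bad, collapse = ", "))
  composition <- composition[composition > 0]
  if (length(composition) == 0 || sum(composition) < 1)
    stop("glycan composition must contain at least one residue")
  comp <- Reduce(`+`, Map(function(name, n) n * .glycan_formula[[name]],
                          names(composition), composition))
  if (form == "reduced-alditol") comp <- comp + .water + .h2
  comp
}

#' Glycan mass (monoisotopic and average)
#'
#' @inheritParams glycan_composition
#' @return a `mass_value`
#' @examples
#' glycan_mass(c(hexnac = 1))                       # 223.1056 Da alditol
#' glycan_mass(c(hexnac = 1), form = "bound")       # 203.0794 Da residue
#' @export
glycan_mass <- function(composition, form = c("reduced-alditol", "bound")) {
  .mass_value(glycan_composition(composition, form))
}

#' Neutral mass to m/z
#'
#' Protonation (positive polarity) or deprotonation (negative polarity) with
#' the proton mass, 1.007276 Da.
#'
#' @param mass neutral mass, Da
#' @param charge positive integer charge count
#' @param polarity `"positive"` or `"negative"`
#' @export
to_mz <- function(mass, charge, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  sign <- if (polarity == "positive") 1 else -1
  (mass + sign * charge * .proton_mass) / charge
}

#' m/z back to neutral mass
#' @inheritParams to_mz
#' @param mz observed m/z
#' @export
mass_from_mz <- function(mz, charge, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  sign <- if (polarity == "positive") 1 else -1
  mz * charge - sign * charge * .proton_mass
}

#' Mass constants table
#'
#' Machine-readable export of every elemental and residue constant used by
#' the package, for audit. A copy ships as
#' `inst/extdata/mass_constants.csv`.
#'
#' @return data.frame with columns `kind`, `symbol`, `monoisotopic`,
#'   `average`, `formula`
#' @export
mass_constants <- function() {
  fmt <- function(comp) {
    comp <- comp[comp != 0]
    paste(sprintf("%s%d", names(comp), comp), collapse = "")
  }
  rows <- list()
  for (e in names(.elements)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "element", symbol = e,
      monoisotopic = .elements[[e]]$mass[1],
      average = .elements[[e]]$average, formula = e)
  }
  for (a in names(.aa_formula)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "aa_residue", symbol = a,
      monoisotopic = monoisotopic_mass(.aa_formula[[a]]),
      average = average_mass(.aa_formula[[a]]),
      formula = fmt(.aa_formula[[a]]))
  }
  for (g in names(.glycan_formula)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "glycan_residue", symbol = g,
      monoisotopic = monoisotopic_mass(.glycan_formula[[g]]),
      average = average_mass(.glycan_formula[[g]]),
      formula = fmt(.glycan_formula[[g]]))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "constant", symbol = "water",
    monoisotopic = monoisotopic_mass(.water), average = average_mass(.water),
    formula = "H2O1")
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "constant", symbol = "proton", monoisotopic = .proton_mass,
    average = .proton_mass, formula = "p")
  do.call(rbind, rows)
}
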