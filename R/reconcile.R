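## Cross-level reconciliation: profile correlation, occupancy consolidation,
## contamination diagnosis and the semi-quantitative site x structure table.

#' Squared correlation between two abundance profiles
#'
#' Profiles are mapped onto a common species universe (absent species
#' contribute 0) and the R-squared of the least-squares linear fit between
#' the abundance vectors is returned. Computed on raw proportions, not
#' logits.
#'
#' @param profile_a,profile_b named numeric abundance vectors, or
#'   `quant_profile` objects (their `mean` column is used, keyed by species
#'   or by annotated members)
#' @param universe character vector of species defining the comparison
#'   space; at least 3 species
#' @return R-squared in [0, 1]
#' @export
correlate_profiles <- function(profile_a, profile_b, universe) {
  if (length(universe) < 3)
    stop("species universe must contain at least 3 species (R2 unstable)")
  a <- .profile_vector(profile_a, universe)
  b <- .profile_vector(profile_b, universe)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)^2
}

.profile_vector <- function(profile, universe) {
  if (inherits(profile, "quant_profile") || is.data.frame(profile)) {
    keys <- profile$species
    vals <- profile$mean
    # isomer-group entries may be keyed by their member annotation
    if (!is.null(profile$members)) {
      for (i in seq_along(keys)) {
        mem <- strsplit(profile$members[i], "/", fixed = TRUE)[[1]]
        hit <- intersect(mem, universe)
        if (length(hit) && !keys[i] %in% universe) keys[i] <- hit[1]
      }
    }
    vals <- stats::setNames(vals, keys)
  } else vals <- profile
  out <- stats::setNames(numeric(length(universe)), universe)
  common <- intersect(names(vals), universe)
  out[common] <- vals[common]
  out
}

#' Semi-quantitative abundance bins
#'
#' Maps relative abundances (%) and trace-detection flags to the
#' four-level site x structure notation: `xxxx` >= 20%, `xxx` 2-20%, `xx`
#' quantifiable below 2%, `x` detected-only (trace, non-quantifiable).
#' Thresholds reproduce the published semi-quantitative table from its
#' printed abundances and are configurable.
#'
#' @param abundance numeric vector of relative abundances, %
#' @param trace logical vector: detected but non-quantifiable
#' @param high,intermediate bin thresholds, %
#' @return character vector of bins (`NA` for absent species)
#' @export
semiquant_bin <- function(abundance, trace = rep(FALSE, length(abundance)),
                          high = 20, intermediate = 2) {
  stopifnot(length(abundance) == length(trace), high > intermediate)
  out <- rep(NA_character_, length(abundance))
  detected <- !is.na(abundance) & abundance > 0
  out[detected & trace] <- "x"
  quant <- detected & !trace
  out[quant & abundance >= high] <- "xxxx"
  out[quant & abundance < high & abundance >= intermediate] <- "xxx"
  out[quant & abundance < intermediate] <- "xx"
  out
}

#' Site x structure semi-quantitative table
#'
#' @param site_profiles named list of `quant_profile` objects (one per
#'   site, names like `"nCG Asn71"`)
#' @param panel glycan panel defining the structure rows
#' @inheritParams semiquant_bin
#' @return data.frame: structures as rows, sites as columns, bins as cells
#' @export
semiquant_table <- function(site_profiles, panel = default_glycan_panel(TRUE),
                            high = 20, intermediate = 2) {
  out <- data.frame(structure = panel$name)
  for (site in names(site_profiles)) {
    prof <- site_profiles[[site]]
    idx <- match(panel$name, prof$species)
    out[[site]] <- semiquant_bin(prof$mean[idx], prof$trace[idx],
                                 high, intermediate)
  }
  out
}

#' Diagnose glycome contamination
#'
#' Predicts the released glycome expected from the target protein's site
#' profile alone (restricted to PNGase-F-releasable structures,
#' renormalized) and flags glycome species whose observed abundance exceeds
#' that prediction by more than `threshold` percentage points. Flagged
#' species are attributed to candidate contaminant proteins whose site
#' profiles contain them, or reported `"unattributed"`.
#'
#' @param glycome_profile `quant_profile` from [quantify_glycome()]
#' @param target_profile `quant_profile` of the target site (glycopeptide
#'   stage), or `NULL` when only glycome evidence exists
#' @param contaminant_profiles named list of site `quant_profile`s of
#'   candidate contaminants (may be empty)
#' @param panel glycan panel
#' @param threshold excess abundance (percentage points) that triggers a
#'   flag
#' @return data.frame of flagged species with `observed`, `expected`,
#'   `excess`, `attributed_to`
#' @export
diagnose_contamination <- function(glycome_profile, target_profile = NULL,
                                   contaminant_profiles = list(),
                                   panel = default_glycan_panel(TRUE),
                                   threshold = 5) {
  releasable <- panel$name[pngase_releases(panel)]
  obs <- .profile_vector(glycome_profile, releasable)
  if (!is.null(target_profile)) {
    exp_raw <- .profile_vector(target_profile, releasable)
    expected <- if (sum(exp_raw) > 0) 100 * exp_raw / sum(exp_raw) else exp_raw
  } else {
    expected <- stats::setNames(numeric(length(releasable)), releasable)
  }
  excess <- obs - expected
  flagged <- names(excess)[excess > threshold |
                           (is.null(target_profile) & obs > threshold)]
  if (length(flagged) == 0)
    return(data.frame(species = character(), observed = numeric(),
                      expected = numeric(), excess = numeric(),
                      attributed_to = character()))
  attributed <- vapply(flagged, function(sp) {
    carriers <- names(contaminant_profiles)[vapply(
      contaminant_profiles, function(p) {
        v <- .profile_vector(p, releasable)
        v[sp] > 0
      }, logical(1))]
    if (length(carriers)) paste(carriers, collapse = ",") else "unattributed"
  }, character(1))
  data.frame(species = flagged, observed = obs[flagged],
             expected = expected[flagged], excess = excess[flagged],
             attributed_to = attributed, row.names = NULL)
}
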