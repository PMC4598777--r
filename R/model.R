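## Ground-truth model for the synthetic three-level LC-MS experiments.

#' Construct a ground-truth model
#'
#' @param proteins list of protein entries; each a list with fields `name`,
#'   `sequence` (mature chain), `offset` (unprocessed-chain position of the
#'   first mature residue), `weight` (relative molar abundance),
#'   `cterm_variants` (data.frame `name`, `length` in residues of the mature
#'   chain, `prop_peptide`, `prop_intact`; each proportion column sums to 1),
#'   `glycosites` (list of lists with `position`, `occupancy`, `glycoforms` =
#'   data.frame `glycan`, `proportion` summing to 1), `fixed_mods`, and
#'   `oxidized_met` (unprocessed positions carrying complete oxidation)
#' @param panel glycan panel used to resolve glycan names
#' @param ionization_bias named numeric: positive-mode response factor per
#'   glycan category (`neutral`, `sialylated`)
#' @param noise list: `intensity_cv` (lognormal CV of feature areas),
#'   `mz_ppm` (m/z jitter), `isotope_cv` (jitter on isotope cluster
#'   abundances)
#' @param insource list: `max_fraction` glycan-loss fraction reached at
#'   `v_max`; the fraction is 0 at `v_zero` (200 V) and rises linearly
#' @param trace_threshold relative abundance (%) below which a species is
#'   reported as trace (detected, non-quantifiable)
#' @return object of class `ground_truth_model`
#' @export
ground_truth_model <- function(proteins,
                               panel = default_glycan_panel(include_stubs = TRUE),
                               ionization_bias = c(neutral = 1, sialylated = 0.5),
                               noise = list(intensity_cv = 0.05, mz_ppm = 10,
                                            isotope_cv = 0.02),
                               insource = list(max_fraction = 0.4,
                                               v_zero = 200, v_max = 400),
                               trace_threshold = 0.5) {
  for (p in proteins) {
    for (col in c("prop_peptide", "prop_intact")) {
      s <- sum(p$cterm_variants[[col]])
      if (abs(s - 1) > 1e-9)
        stop(sprintf("%s: %s must sum to 1 (got %.6f)", p$name, col, s))
    }
    for (g in p$glycosites) {
      s <- sum(g$glycoforms$proportion)
      if (abs(s - 1) > 1e-9)
        stop(sprintf("%s site %d: glycoform proportions must sum to 1",
                     p$name, g$position))
      if (g$occupancy < 0 || g$occupancy > 1)
        stop("occupancy must lie in [0, 1]")
      missing <- setdiff(g$glycoforms$glycan, panel$name)
      if (length(missing))
        stop("glycoforms not in panel: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(proteins = proteins, panel = panel,
                 ionization_bias = ionization_bias, noise = noise,
                 insource = insource, trace_threshold = trace_threshold),
            class = "ground_truth_model")
}

#' In-source glycan-loss fraction at a fragmentor voltage
#'
#' Zero at and below 200 V, rising linearly to `max_fraction` at `v_max`.
#' @param model a `ground_truth_model`
#' @param voltage fragmentor voltage, V (valid 150-400)
#' @export
insource_decay_fraction <- function(model, voltage) {
  if (voltage < 150 || voltage > 400)
    stop("fragmentor voltage must lie in 150-400 V")
  p <- model$insource
  f <- p$max_fraction * max(0, (voltage - p$v_zero)) / (p$v_max - p$v_zero)
  min(max(f, 0), 1)
}

#' The default ground-truth model
#'
#' Encodes the published study conditions as simulator defaults:
#' \itemize{
#'  \item cathepsin G-like target with a fully occupied Asn71 carrying
#'    GlcNAcb 55.2, Fuca1,6GlcNAcb 22.7, M1 10.6, M1F 7.9 and M2 3.7 (%),
#'    plus trace M2F and five trace sialylated monoantennary structures
#'    (0.1% each; the vector is renormalized to sum to 1);
#'  \item two C-terminal truncation variants, Arg243/Ser244, at 57.8/42.2
#'    (peptide level) and 61.9/38.1 (intact level);
#'  \item complete Met152 oxidation;
#'  \item co-purified azurocidin-like and elastase-like contaminants whose
#'    sites are dominated by M2F and also carry the glycome-only M0F/M1F/M3F
#'    species.
#' }
#'
#' @param occupancy Asn71 site occupancy of the target protein
#' @param contaminants include the two contaminant glycoproteins
#' @param fixtures named sequences as returned by [load_protein_fixtures()]
#' @return a `ground_truth_model`
#' @export
default_study_model <- function(occupancy = 1.0, contaminants = TRUE,
                                fixtures = load_protein_fixtures()) {
  need <- c("CTSG_SYN", "AZU1_SYN", "ELANE_SYN")
  if (!all(need %in% names(fixtures)))
    stop("fixtures must contain ", paste(need, collapse = ", "),
         "; see load_protein_fixtures()")
  gf <- function(glycan, proportion) {
    data.frame(glycan = glycan, proportion = proportion / sum(proportion))
  }
  asn71 <- gf(
    c("GlcNAcb", "FucGlcNAcb", "M1", "M1F", "M2",
      "M2F", "MA3F-S6", "MA3F-S3", "MA3-S6", "MA2F-S6", "MA2F-S3"),
    c(55.2, 22.7, 10.6, 7.9, 3.7, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  # mature chain 21..244 of the unprocessed 255-residue precursor
  full <- fixtures[["CTSG_SYN"]]
  ncg_mature <- substr(full, 21, 244)
  ncg <- list(
    name = "nCG", sequence = ncg_mature, offset = 21L, weight = 1.0,
    cterm_variants = data.frame(
      name = c("Arg243", "Ser244"),
      length = c(nchar(ncg_mature) - 1L, nchar(ncg_mature)),
      prop_peptide = c(0.578, 0.422),
      prop_intact = c(0.619, 0.381)),
    glycosites = list(list(position = 71L, occupancy = occupancy,
                           glycoforms = asn71)),
    fixed_mods = character(),
    oxidized_met = 152L,
    n_disulfides = 3L)
  azu <- list(
    name = "azurocidin", sequence = fixtures[["AZU1_SYN"]], offset = 1L,
    weight = 0.6,
    cterm_variants = data.frame(name = "full",
                                length = nchar(fixtures[["AZU1_SYN"]]),
                                prop_peptide = 1, prop_intact = 1),
    glycosites = list(
      list(position = 126L, occupancy = 1,
           glycoforms = gf(c("M2F", "M0F", "M3F"), c(0.70, 0.18, 0.12))),
      list(position = 171L, occupancy = 1,
           glycoforms = gf(c("M2F", "M1F", "M0F", "M3F"),
                           c(0.75, 0.015, 0.12, 0.115)))),
    fixed_mods = character(), oxidized_met = integer(), n_disulfides = 0L)
  ne <- list(
    name = "NE", sequence = fixtures[["ELANE_SYN"]], offset = 1L,
    weight = 0.5,
    cterm_variants = data.frame(name = "full",
                                length = nchar(fixtures[["ELANE_SYN"]]),
                                prop_peptide = 1, prop_intact = 1),
    glycosites = list(
      list(position = 124L, occupancy = 1,
           glycoforms = gf(c("M2F", "M0F", "M3F"), c(0.78, 0.12, 0.10))),
      list(position = 173L, occupancy = 1,
           glycoforms = gf(c("M2F", "M0F", "M3F"), c(0.85, 0.08, 0.07)))),
    fixed_mods = character(), oxidized_met = integer(), n_disulfides = 0L)
  proteins <- if (contaminants) list(ncg, azu, ne) else list(ncg)
  ground_truth_model(proteins)
}
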