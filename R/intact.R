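## Intact-glycoprotein stage: charge-envelope deconvolution of multi-charge
## ESI spectra, combinatorial proteoform matching, isotopic-distribution
## scoring and EIC-based proteoform quantitation.
##
## Deconvolution is a defined charge-envelope clustering (each reported
## neutral mass is supported by at least two consecutive charge states),
## replacing vendor maximum-entropy deconvolution while preserving its
## contract: neutral masses plus summed intensities. The matching currency
## at this level is the average mass (the deconvoluted apex of an
## unresolved-envelope QTOF measurement); monoisotopic masses are carried
## for the glycan and peptide levels.

#' Charge-envelope deconvolution of an ESI spectrum
#'
#' For every candidate charge in `z_range`, each peak is converted to a
#' neutral-mass hypothesis; hypotheses agreeing within `tol_da` across at
#' least `min_states` consecutive charge states form an envelope. The
#' envelope's neutral mass is the intensity-weighted mean, its intensity the
#' sum over member peaks.
#'
#' @param peaks data.frame with `mz` and `intensity` (positive mode)
#' @param z_range integer range of candidate charges
#' @param tol_da neutral-mass agreement tolerance, Da
#' @param min_states minimum number of consecutive charge states
#' @return data.frame `neutral_mass`, `intensity`, `n_states`, `z_min`,
#'   `z_max`; empty (with a warning) when no envelope is found
#' @export
deconvolute <- function(peaks, z_range = c(8L, 30L), tol_da = 1.0,
                        min_states = 2L) {
  if (nrow(peaks) < 2) {
    warning("fewer than 2 peaks: no envelope can be established")
    return(data.frame(neutral_mass = numeric(), intensity = numeric(),
                      n_states = integer(), z_min = integer(),
                      z_max = integer()))
  }
  zs <- seq.int(z_range[1], z_range[2])
  hyp <- do.call(rbind, lapply(zs, function(z) data.frame(
    mass = mass_from_mz(peaks$mz, z, "positive"), z = z,
    intensity = peaks$intensity, peak = seq_len(nrow(peaks)))))
  hyp <- hyp[order(hyp$mass), ]
  # single-linkage grouping of the sorted mass hypotheses
  grp <- cumsum(c(TRUE, diff(hyp$mass) > tol_da))
  envelope_of <- function(g) {
    uz <- sort(unique(g$z))
    if (length(uz) < min_states) return(NULL)
    # longest run of consecutive charge states within the group
    runs <- split(uz, cumsum(c(TRUE, diff(uz) != 1)))
    best <- runs[[which.max(lengths(runs))]]
    if (length(best) < min_states) return(NULL)
    gg <- g[g$z %in% best, ]
    # one peak per charge state: keep the most intense hypothesis
    gg <- do.call(rbind, lapply(split(gg, gg$z), function(x)
      x[which.max(x$intensity), ]))
    gg
  }
  cand <- Filter(Negate(is.null), lapply(split(hyp, grp), envelope_of))
  # harmonic suppression: envelopes are accepted greedily by evidence
  # (number of charge states, then intensity); an envelope whose peaks are
  # already claimed by a stronger envelope is a charge-assignment harmonic
  ord <- order(vapply(cand, nrow, integer(1)),
               vapply(cand, function(g) sum(g$intensity), numeric(1)),
               decreasing = TRUE)
  claimed <- logical(nrow(peaks))
  out <- list()
  for (g in cand[ord]) {
    free <- !claimed[g$peak]
    if (sum(free) < min_states || mean(free) < 0.5) next
    gg <- g[free, ]
    uz <- sort(unique(gg$z))
    runs <- split(uz, cumsum(c(TRUE, diff(uz) != 1)))
    best <- runs[[which.max(lengths(runs))]]
    if (length(best) < min_states) next
    gg <- gg[gg$z %in% best, ]
    claimed[gg$peak] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      neutral_mass = sum(gg$mass * gg$intensity) / sum(gg$intensity),
      intensity = sum(gg$intensity), n_states = nrow(gg),
      z_min = min(gg$z), z_max = max(gg$z))
  }
  if (length(out) == 0) {
    warning("no charge envelope found")
    return(data.frame(neutral_mass = numeric(), intensity = numeric(),
                      n_states = integer(), z_min = integer(),
                      z_max = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$neutral_mass), ]
}

#' Combinatorial proteoform space of the target protein
#'
#' Every C-terminal truncation variant crossed with the glycan panel plus
#' the aglycosylated form, at the protein's fixed oxidation state. Native
#' runs subtract two hydrogens per disulfide bond.
#'
#' @param model a `ground_truth_model`
#' @param protein protein name (default: the target, first model entry)
#' @return data.frame with `id`, `cterm`, `glycan`, `oxidized`,
#'   `average_mass`, `monoisotopic_mass` and a `composition` list column
#' @export
proteoform_space <- function(model, protein = NULL) {
  p <- if (is.null(protein)) model$proteins[[1]] else
    Filter(function(x) x$name == protein, model$proteins)[[1]]
  cv <- p$cterm_variants
  pan <- model$panel
  rows <- list()
  for (i in seq_len(nrow(cv))) {
    vseq <- substr(p$sequence, 1L, cv$length[i])
    n_ox <- sum(p$oxidized_met >= p$offset &
                p$oxidized_met <= p$offset + cv$length[i] - 1L)
    base <- peptide_composition(vseq) +
      n_ox * c(C = 0, H = 0, N = 0, O = 1, S = 0) -
      p$n_disulfides * c(C = 0, H = 2, N = 0, O = 0, S = 0)
    suffix <- if (n_ox > 0) "-ox" else ""
    glycans <- c(pan$name, NA_character_)
    for (gl in glycans) {
      comp <- base
      if (!is.na(gl)) {
        pr <- pan[pan$name == gl, ]
        comp <- comp + glycan_composition(
          c(hex = pr$hex, hexnac = pr$hexnac, dhex = pr$dhex,
            neuac = pr$neuac), form = "bound")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s|%s|%s%s", p$name, cv$name[i],
                     if (is.na(gl)) "aglycosylated" else gl, suffix),
        cterm = cv$name[i], glycan = gl, oxidized = n_ox > 0,
        average_mass = average_mass(comp),
        monoisotopic_mass = monoisotopic_mass(comp),
        composition = I(list(comp)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match deconvoluted neutral masses against a proteoform space
#'
#' Nearest average mass within `tol_ppm`; when two proteoforms fall within
#' tolerance both are reported and flagged ambiguous. Matched proteoforms
#' differing by one serine residue (+87.08 Da average) are annotated as
#' C-terminal-variant partners ("+87 Da"), and pairs differing by one oxygen
#' (+15.999 Da) as oxidation partners ("+16 Da").
#'
#' @param masses data.frame from [deconvolute()]
#' @param space data.frame from [proteoform_space()]
#' @param tol_ppm matching tolerance, ppm of the neutral mass
#' @return data.frame of matches with `delta_87_partner`, `delta_16_partner`
#'   annotation columns
#' @export
match_proteoforms <- function(masses, space, tol_ppm = 50) {
  out <- list()
  for (i in seq_len(nrow(masses))) {
    m <- masses$neutral_mass[i]
    err <- space$average_mass - m
    tol <- tol_ppm * 1e-6 * m
    hit <- which(abs(err) <= tol)
    if (length(hit) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        neutral_mass = m, intensity = masses$intensity[i],
        id = NA_character_, cterm = NA_character_, glycan = NA_character_,
        mass_error_ppm = NA_real_, ambiguous = FALSE)
      next
    }
    best <- hit[which.min(abs(err[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      neutral_mass = m, intensity = masses$intensity[i],
      id = space$id[best], cterm = space$cterm[best],
      glycan = space$glycan[best],
      mass_error_ppm = 1e6 * (m - space$average_mass[best]) /
        space$average_mass[best],
      ambiguous = length(hit) > 1)
  }
  res <- do.call(rbind, out)
  # delta-mass pairing links on the matched masses (symmetric)
  ser <- average_mass(.aa_formula$S)      # +87.08 average
  oxd <- average_mass(c(O = 1))           # +16.00
  res$delta_87_partner <- NA_character_
  res$delta_16_partner <- NA_character_
  for (i in seq_len(nrow(res))) {
    d <- res$neutral_mass - res$neutral_mass[i]
    j87 <- which(abs(abs(d) - ser) < 0.5 & seq_along(d) != i)
    j16 <- which(abs(abs(d) - oxd) < 0.5 & seq_along(d) != i)
    if (length(j87)) res$delta_87_partner[i] <- res$id[j87[1]]
    if (length(j16)) res$delta_16_partner[i] <- res$id[j16[1]]
  }
  res
}

#' Isotopic-distribution fit score
#'
#' Total-variation similarity `1 - 0.5 * sum(|obs - theo|)` over aligned
#' isotopologue bins (nearest-mass alignment within `align_da`); 1 for a
#' perfect match, 0 for disjoint patterns. Both patterns are renormalized.
#'
#' @param observed,theoretical data.frames with `mass` and `abundance`
#' @param align_da bin alignment tolerance, Da
#' @return score in [0, 1]
#' @export
isotope_fit <- function(observed, theoretical, align_da = 0.5) {
  if (nrow(observed) < 1 || nrow(theoretical) < 1)
    stop("isotope fit undefined for an unresolved (empty) cluster")
  obs <- observed$abundance / sum(observed$abundance)
  theo <- theoretical$abundance / sum(theoretical$abundance)
  idx <- vapply(observed$mass, function(m) {
    j <- which.min(abs(theoretical$mass - m))
    if (abs(theoretical$mass[j] - m) <= align_da) j else NA_integer_
  }, integer(1))
  overlap <- 0
  used <- rep(FALSE, length(theo))
  for (i in seq_along(obs)) {
    j <- idx[i]
    if (!is.na(j) && !used[j]) {
      overlap <- overlap + min(obs[i], theo[j])
      used[j] <- TRUE
    }
  }
  # 1 - TV distance == sum of bin-wise minima for aligned distributions
  overlap
}

#' Proteoform quantitation from matched envelopes
#'
#' Marginal EIC-area profiles over (a) C-terminal truncation variants and
#' (b) Asn-site glycoforms summed over variants, as mean +/- SD across
#' replicate runs.
#'
#' @param runs list of intact-level `synthetic_run`s (replicates)
#' @param model a `ground_truth_model`
#' @param tol_ppm passed to [match_proteoforms()]
#' @return list with `cterm` and `glycoform` data.frames (`mean` in %,
#'   `sd`), and `aglycosylated_fraction` (% of total intensity matched to
#'   aglycosylated proteoforms)
#' @export
quantify_proteoforms <- function(runs, model, tol_ppm = 50) {
  if (inherits(runs, "synthetic_run")) runs <- list(runs)
  space <- proteoform_space(model)
  per_rep <- lapply(runs, function(run) {
    dec <- deconvolute(run$features[, c("mz", "intensity")])
    mm <- match_proteoforms(dec, space, tol_ppm)
    mm <- mm[!is.na(mm$id), ]
    if (nrow(mm) == 0) stop("no proteoform matched")
    list(
      cterm = tapply(mm$intensity, mm$cterm, sum),
      glyco = if (any(!is.na(mm$glycan)))
        tapply(mm$intensity[!is.na(mm$glycan)], mm$glycan[!is.na(mm$glycan)],
               sum) else numeric(),
      aglyco = sum(mm$intensity[is.na(mm$glycan)]) / sum(mm$intensity))
  })
  tab <- function(field) {
    keys <- sort(unique(unlist(lapply(per_rep,
                                      function(x) names(x[[field]])))))
    mat <- sapply(per_rep, function(x) {
      v <- stats::setNames(numeric(length(keys)), keys)
      v[names(x[[field]])] <- x[[field]]
      100 * v / sum(v)
    })
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(keys))
    out <- data.frame(species = keys, mean = rowMeans(mat),
                      sd = apply(mat, 1, stats::sd))
    out[order(-out$mean), ]
  }
  list(cterm = tab("cterm"), glycoform = tab("glyco"),
       aglycosylated_fraction = 100 *
         mean(vapply(per_rep, `[[`, numeric(1), "aglyco")))
}
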