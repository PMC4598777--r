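## Glycopeptide-level identification and site-specific quantitation.
##
## CID of a glycopeptide fragments the glycan: the diagnostic ions are the
## Y-ladder (peptide + 0..n glycan residues) and low-mass oxonium B ions,
## with weak backbone b/y ions. ETD fragments the backbone into c/z ions
## with the glycan retained intact, which is what localizes the site.

.nh3 <- 17.026549
.oxonium <- c(HexNAc = 204.086649, HexNAcFrag = 186.076084,
              NeuAc = 292.102693, NeuAcH2O = 274.092128,
              HexHexNAc = 366.139472)

.as_glycomp <- function(glycan) {
  full <- c(hex = 0, hexnac = 0, dhex = 0, neuac = 0)
  bad <- setdiff(names(glycan), names(full))
  if (length(bad)) stop("unknown monosaccharides: ", paste(bad, collapse = ", "))
  full[names(glycan)] <- glycan
  full
}

# canonical degradation order of the flat glycan model: core GlcNAc, core
# fucose, second GlcNAc, mannoses/hexoses, antenna GlcNAc, sialic acid
.glycan_residue_order <- function(glycan) {
  res <- character()
  masses <- c(hexnac = 203.079373, hex = 162.052824, dhex = 146.057909,
              neuac = 291.095417)
  n_hexnac <- glycan[["hexnac"]]
  res <- c(res, "hexnac")
  if (glycan[["dhex"]] > 0) res <- c(res, rep("dhex", glycan[["dhex"]]))
  if (n_hexnac >= 2) res <- c(res, "hexnac")
  if (glycan[["hex"]] > 0) res <- c(res, rep("hex", glycan[["hex"]]))
  if (n_hexnac >= 3) res <- c(res, rep("hexnac", n_hexnac - 2L))
  if (glycan[["neuac"]] > 0) res <- c(res, rep("neuac", glycan[["neuac"]]))
  masses[res]
}

#' Theoretical fragment ions of a (glyco)peptide
#'
#' @param sequence peptide amino-acid string
#' @param glycan named monosaccharide counts of the attached glycan (bound
#'   form), or `NULL` for a plain peptide
#' @param site_index glycosylation site position within the peptide (1-based)
#' @param mode `"CID"` or `"ETD"`
#' @param max_charge fragment charges reported, 1..`max_charge`
#' @param fixed_mods passed to [peptide_mass()]
#' @return data.frame: `ion` (label), `series`, `index`, `mz`, `charge`,
#'   `tier` (relative intensity tier used by the simulator)
#' @export
theoretical_fragments <- function(sequence, glycan = NULL, site_index = NA,
                                  mode = c("CID", "ETD"), max_charge = 1L,
                                  fixed_mods = character()) {
  mode <- match.arg(mode)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  pep <- peptide_mass(sequence, fixed_mods)$monoisotopic
  res_mass <- vapply(.aa_formula[aa], monoisotopic_mass, numeric(1))
  # fixed mods folded in by spreading the total delta is wrong per-fragment;
  # apply per-residue instead
  for (m in fixed_mods) {
    tgt <- .mod_delta[[m]]$target
    res_mass[aa %in% tgt] <- res_mass[aa %in% tgt] +
      monoisotopic_mass(pmax(.mod_delta[[m]]$delta, 0)) -
      monoisotopic_mass(pmax(-.mod_delta[[m]]$delta, 0))
  }
  if (!is.null(glycan)) glycan <- .as_glycomp(glycan)
  has_glycan <- !is.null(glycan) && sum(glycan) > 0
  glyc_total <- if (has_glycan) sum(.glycan_residue_order(glycan)) else 0
  rows <- list()
  emit <- function(series, index, neutral, tier) {
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        ion = sprintf("%s%d^%d+", series, index, z), series = series,
        index = index, mz = to_mz(neutral, z, "positive"), charge = z,
        tier = tier)
    }
  }
  if (mode == "CID") {
    if (has_glycan) {
      ladder <- .glycan_residue_order(glycan)
      emit("Y", 0L, pep, 100)
      for (k in seq_along(ladder))
        emit("Y", k, pep + sum(ladder[seq_len(k)]), 90)
      ox <- .oxonium[c("HexNAc", "HexNAcFrag")]
      if (glycan[["neuac"]] > 0) ox <- c(ox, .oxonium[c("NeuAc", "NeuAcH2O")])
      if (glycan[["hex"]] > 0) ox <- c(ox, .oxonium["HexHexNAc"])
      for (j in seq_along(ox)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ion = sprintf("B(%s)", names(ox)[j]), series = "B", index = j,
          mz = unname(ox[j]), charge = 1L, tier = 80)
      }
    }
    # weak backbone b/y (glycan not retained under CID)
    bseries <- cumsum(res_mass)[-n]
    yseries <- rev(cumsum(rev(res_mass)))[-1] + 18.010565
    for (i in seq_along(bseries)) emit("b", i, bseries[i], 10)
    for (i in seq_along(yseries)) emit("y", i, yseries[n - i], 10)
  } else {
    # ETD c/z with the glycan retained on the site-containing fragment
    cs <- cumsum(res_mass)
    for (i in seq_len(n - 1)) {
      add <- if (has_glycan && !is.na(site_index) && i >= site_index)
        glyc_total else 0
      emit("c", i, cs[i] + .nh3 + add, 50)
    }
    zs <- rev(cumsum(rev(res_mass)))
    for (j in seq_len(n - 1)) {
      first_res <- n - j + 1L
      add <- if (has_glycan && !is.na(site_index) && site_index >= first_res)
        glyc_total else 0
      emit("z", j, zs[first_res] + 18.010565 - .nh3 + add, 50)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate (glyco)peptide species for MS1/MS2 assignment
#'
#' Built from the protein sequences and the glycan panel alone (digest of
#' every protein, site-covering peptides crossed with the full panel
#' including the PNGase-F-resistant stubs, non-glycosylated site peptides,
#' and the C-terminal variant peptides) - independently of any ground-truth
#' proportions.
#'
#' @param model a `ground_truth_model` (only sequences and panel are used)
#' @return data.frame of candidates with theoretical monoisotopic masses
#' @export
glycopeptide_targets <- function(model) {
  rows <- list()
  for (p in model$proteins) {
    for (g in p$glycosites) {
      sp <- .site_peptide(p, g$position)
      pep_mass <- peptide_mass(sp$sequence, p$fixed_mods)$monoisotopic
      pan <- model$panel
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("%s|Asn%d|%s", p$name, g$position, pan$name),
        protein = p$name, site = g$position, glycan = pan$name,
        peptide = sp$sequence, cterm = NA_character_,
        neutral_mass = pep_mass + pan$mass_bound)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("%s|Asn%d|nonglycosylated", p$name, g$position),
        protein = p$name, site = g$position, glycan = NA_character_,
        peptide = sp$sequence, cterm = NA_character_,
        neutral_mass = pep_mass)
    }
    cv <- p$cterm_variants
    if (nrow(cv) > 1) {
      for (i in seq_len(nrow(cv))) {
        cp <- .cterm_peptide(p, cv$length[i])
        rows[[length(rows) + 1L]] <- data.frame(
          species = sprintf("%s|cterm|%s", p$name, cp$sequence),
          protein = p$name, site = NA_integer_, glycan = NA_character_,
          peptide = cp$sequence, cterm = cv$name[i],
          neutral_mass = peptide_mass(cp$sequence, p$fixed_mods)$monoisotopic)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign MS1 features to candidate (glyco)peptide species
#'
#' Each feature is matched to the candidate whose theoretical m/z (at the
#' feature's charge, positive mode) falls within `tol_da`; features matching
#' no candidate are left unassigned, features matching several distinct
#' masses are flagged ambiguous.
#'
#' @param run a glycopeptide-level `synthetic_run` (or a compatible feature
#'   table read with [read_feature_csv()])
#' @param targets candidates from [glycopeptide_targets()]
#' @param tol_da MS1 matching tolerance, Da
#' @return feature table with `assigned_species`, `mass_error_da`,
#'   `ambiguous` columns
#' @export
assign_glycopeptides <- function(run, targets, tol_da = 0.3) {
  if (run$level != "glycopeptide") stop("run level must be 'glycopeptide'")
  if (tol_da <= 0) stop("tolerance must be positive")
  feats <- run$features
  feats$assigned_species <- NA_character_
  feats$mass_error_da <- NA_real_
  feats$ambiguous <- FALSE
  for (i in seq_len(nrow(feats))) {
    theo_mz <- to_mz(targets$neutral_mass, feats$z[i], "positive")
    err <- feats$mz[i] - theo_mz
    hit <- which(abs(err) <= tol_da)
    if (length(hit) == 0) next
    masses <- unique(round(targets$neutral_mass[hit], 4))
    best <- hit[which.min(abs(err[hit]))]
    feats$assigned_species[i] <- targets$species[best]
    feats$mass_error_da[i] <- err[best]
    feats$ambiguous[i] <- length(masses) > 1
  }
  feats
}

#' Match fragment spectra against candidate species
#'
#' Candidates within `tol_ms1` of the precursor neutral mass are scored by
#' matched fragment-ion count at `tol_ms2`; the best candidate wins, ties
#' broken by precursor mass error. A site localization verdict is issued
#' only for ETD spectra in which matched c/z ions bracket the glycosite with
#' the glycan-consistent mass shift.
#'
#' @param spectra list of spectra as produced by [simulate_run()] or
#'   [read_mgf()]
#' @param model a `ground_truth_model` (sequences + panel)
#' @param tol_ms1,tol_ms2 tolerances in Da
#' @return data.frame, one row per spectrum
#' @export
match_spectra <- function(spectra, model, tol_ms1 = 0.3, tol_ms2 = 0.5) {
  if (tol_ms1 <= 0 || tol_ms2 <= 0) stop("tolerances must be positive")
  targets <- glycopeptide_targets(model)
  out <- list()
  for (s in spectra) {
    prec_neutral <- mass_from_mz(s$precursor_mz, s$charge, "positive")
    cand <- which(abs(targets$neutral_mass - prec_neutral) <= tol_ms1)
    mode <- if (!is.null(s$mode)) s$mode else "CID"
    if (length(cand) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        title = if (!is.null(s$species)) s$species else s$title, mode = mode,
        matched_species = NA_character_, n_matched = 0L, n_theoretical = 0L,
        localized = FALSE)
      next
    }
    best <- NULL
    for (k in cand) {
      gl <- targets$glycan[k]
      glycomp <- if (!is.na(gl)) {
        pr <- .panel_rows(model, gl)
        c(hex = pr$hex, hexnac = pr$hexnac, dhex = pr$dhex, neuac = pr$neuac)
      } else NULL
      site_idx <- if (!is.na(targets$site[k]))
        .site_index_in_peptide(model, targets$protein[k], targets$site[k],
                               targets$peptide[k]) else NA
      prot <- Filter(function(p) p$name == targets$protein[k],
                     model$proteins)[[1]]
      theo <- theoretical_fragments(targets$peptide[k], glycan = glycomp,
                                    site_index = site_idx, mode = mode,
                                    max_charge = max(1L, s$charge - 1L),
                                    fixed_mods = prot$fixed_mods)
      d <- outer(s$peaks$mz, theo$mz, function(a, b) abs(a - b))
      matched <- apply(d, 2, min) <= tol_ms2
      score <- sum(matched)
      loc <- FALSE
      if (mode == "ETD" && !is.na(site_idx) && !is.null(glycomp)) {
        cm <- theo$series == "c" & matched
        zm <- theo$series == "z" & matched
        n_res <- nchar(targets$peptide[k])
        loc <- any(theo$index[cm] >= site_idx) &&
          (any(theo$index[cm] < site_idx) ||
           any(theo$index[zm] <= n_res - site_idx)) &&
          any(theo$index[zm] > n_res - site_idx)
      }
      rec <- list(k = k, score = score,
                  err = abs(targets$neutral_mass[k] - prec_neutral),
                  n_theo = nrow(theo), loc = loc)
      if (is.null(best) || rec$score > best$score ||
          (rec$score == best$score && rec$err < best$err)) best <- rec
    }
    out[[length(out) + 1L]] <- data.frame(
      title = if (!is.null(s$species)) s$species else s$title, mode = mode,
      matched_species = targets$species[best$k], n_matched = best$score,
      n_theoretical = best$n_theo, localized = best$loc)
  }
  do.call(rbind, out)
}

#' Site-specific glycoform profile and occupancy from EIC areas
#'
#' For one glycosite, sums assigned feature areas over all observed charge
#' states per glycoform and divides by the total site EIC, assuming equal
#' ionization efficiencies. Occupancy is the glycosylated fraction of the
#' (glycosylated + non-glycosylated) site-peptide EIC; when no
#' non-glycosylated form is observed the site is reported fully occupied.
#' With several replicate runs the profile is mean +/- SD.
#'
#' @param runs list of glycopeptide-level `synthetic_run`s (replicates)
#' @param model a `ground_truth_model` (sequences + panel)
#' @param protein,site site selector (defaults to the target protein's site)
#' @param tol_da MS1 tolerance passed to [assign_glycopeptides()]
#' @return object of class `quant_profile`: data.frame `species`,
#'   `mean` (%), `sd`, `trace`; attributes `occupancy` (fraction),
#'   `occupancy_sd`, `site`, `protein`
#' @export
site_profile <- function(runs, model, protein = NULL, site = NULL,
                         tol_da = 0.3) {
  if (inherits(runs, "synthetic_run")) runs <- list(runs)
  if (length(runs) < 1) stop("at least one replicate run is required")
  if (is.null(protein)) protein <- model$proteins[[1]]$name
  if (is.null(site)) site <- model$proteins[[1]]$glycosites[[1]]$position
  targets <- glycopeptide_targets(model)
  per_rep <- lapply(runs, function(run) {
    a <- assign_glycopeptides(run, targets, tol_da)
    a <- a[!is.na(a$assigned_species), ]
    info <- targets[match(a$assigned_species, targets$species), ]
    sel <- !is.na(info$site) & info$site == site & info$protein == protein
    a <- a[sel, ]; info <- info[sel, ]
    if (nrow(a) == 0)
      stop(sprintf("site %s/Asn%d never observed", protein, site))
    glyco <- !is.na(info$glycan)
    tot_glyco <- sum(a$intensity[glyco])
    occ <- tot_glyco / sum(a$intensity)
    shares <- tapply(a$intensity[glyco], info$glycan[glyco], sum)
    list(occ = occ, shares = 100 * shares / sum(shares))
  })
  species <- sort(unique(unlist(lapply(per_rep, function(x) names(x$shares)))))
  mat <- sapply(per_rep, function(x) {
    v <- stats::setNames(numeric(length(species)), species)
    v[names(x$shares)] <- x$shares
    v
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(species))
  occs <- vapply(per_rep, `[[`, numeric(1), "occ")
  prof <- data.frame(species = species,
                     mean = rowMeans(mat),
                     sd = apply(mat, 1, stats::sd))
  prof$trace <- prof$mean < model$trace_threshold
  prof <- prof[order(-prof$mean), ]
  rownames(prof) <- NULL
  structure(prof,
            class = c("quant_profile", "data.frame"),
            occupancy = mean(occs), occupancy_sd = stats::sd(occs),
            protein = protein, site = site)
}

#' C-terminal truncation-variant ratio from peptide EIC areas
#'
#' Quantifies the relative abundance of the C-terminal variant peptides
#' (e.g. IRTTMR vs IRTTMRS) summed over all observed charge states.
#'
#' @inheritParams site_profile
#' @return data.frame `cterm`, `peptide`, `mean` (%), `sd`
#' @export
cterm_ratio <- function(runs, model, protein = NULL, tol_da = 0.3) {
  if (inherits(runs, "synthetic_run")) runs <- list(runs)
  if (is.null(protein)) protein <- model$proteins[[1]]$name
  targets <- glycopeptide_targets(model)
  ct <- targets[!is.na(targets$cterm) & targets$protein == protein, ]
  if (nrow(ct) == 0) stop("protein has no C-terminal variant peptides")
  mat <- sapply(runs, function(run) {
    a <- assign_glycopeptides(run, targets, tol_da)
    areas <- vapply(ct$species, function(sp)
      sum(a$intensity[!is.na(a$assigned_species) &
                      a$assigned_species == sp]), numeric(1))
    100 * areas / sum(areas)
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(ct))
  data.frame(cterm = ct$cterm, peptide = ct$peptide,
             mean = rowMeans(mat), sd = apply(mat, 1, stats::sd))
}

#' @export
print.quant_profile <- function(x, ...) {
  occ <- attr(x, "occupancy")
  if (!is.null(attr(x, "site")))
    cat(sprintf("site profile: %s Asn%d\n", attr(x, "protein"),
                attr(x, "site")))
  print.data.frame(cbind(x), digits = 3)
  if (!is.null(occ)) cat(sprintf("occupancy: %.1f%%\n", 100 * occ))
  invisible(x)
}
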