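## Synthetic LC-MS run generator for the three acquisition levels.
##
## Chromatographic peaks are represented as single apex features whose area
## equals the feature intensity: EIC areas are the only quantity the
## downstream stages consume. Charge envelopes are deterministic per level;
## intensities are split across charge states by a fixed multinomial and
## perturbed by lognormal noise.

.charge_split <- list(
  glycome = c(`1` = 0.7, `2` = 0.3),
  glycopeptide = c(`1` = 0.2, `2` = 0.5, `3` = 0.3),
  intact = {
    z <- 15:25
    w <- 6 - abs(z - 20)
    stats::setNames(w / sum(w), z)
  })

.rt_class_mean <- c("chitobiose-stub" = 12, "paucimannose" = 18,
                    "monoantennary-complex" = 30)

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

.bias_for <- function(model, panel_rows) {
  ifelse(panel_rows$neuac > 0, model$ionization_bias[["sialylated"]],
         model$ionization_bias[["neutral"]])
}

.panel_rows <- function(model, names) {
  idx <- match(names, model$panel$name)
  if (anyNA(idx)) stop("glycan not in panel: ",
                       paste(names[is.na(idx)], collapse = ", "))
  model$panel[idx, , drop = FALSE]
}

# fully specific site-covering chymotryptic peptide of a protein
.site_peptide <- function(protein, position) {
  peps <- digest(protein$sequence, missed_cleavages = 0L, specificity = "full",
                 protein = protein$name, offset = protein$offset)
  hit <- peps[!is.na(peps$glycosite) & peps$glycosite == position, ]
  if (nrow(hit) == 0)
    stop(sprintf("%s: no fully specific peptide covers site %d",
                 protein$name, position))
  hit[1, ]
}

# shortest fully-specific C-terminal peptide of length >= min_length
.cterm_peptide <- function(protein, variant_length, min_length = 4L) {
  vseq <- substr(protein$sequence, 1L, variant_length)
  peps <- digest(vseq, missed_cleavages = 2L, specificity = "full",
                 protein = protein$name, offset = protein$offset)
  endpos <- protein$offset + variant_length - 1L
  cand <- peps[peps$end == endpos & nchar(peps$sequence) >= min_length, ]
  cand[which.min(nchar(cand$sequence)), ]
}

#' Ground-truth species tables per acquisition level
#'
#' Enumerates the species a level observes, with theoretical neutral masses
#' and noise-free abundances (molar weight x proportion x occupancy). Used
#' by the generator, and by tests as the provenance reference.
#'
#' @param model a `ground_truth_model`
#' @param level `"glycome"`, `"glycopeptide"` or `"intact"`
#' @return data.frame with one row per ground-truth species
#' @export
ground_truth_species <- function(model,
                                 level = c("glycome", "glycopeptide", "intact")) {
  level <- match.arg(level)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  if (level == "glycome") {
    for (p in model$proteins) {
      for (g in p$glycosites) {
        pr <- .panel_rows(model, g$glycoforms$glycan)
        rel <- pngase_releases(pr)
        if (!any(rel)) next
        add(data.frame(
          species = pr$name[rel], protein = p$name, site = g$position,
          glycan = pr$name[rel], peptide = NA_character_,
          cterm = NA_character_,
          neutral_mass = pr$mass_alditol[rel],
          rt = .rt_class_mean[pr$class[rel]],
          abundance = p$weight * g$occupancy * g$glycoforms$proportion[rel],
          bias = 1))
      }
    }
  } else if (level == "glycopeptide") {
    for (p in model$proteins) {
      for (g in p$glycosites) {
        sp <- .site_peptide(p, g$position)
        pep_mass <- peptide_mass(sp$sequence, p$fixed_mods)$monoisotopic
        pr <- .panel_rows(model, g$glycoforms$glycan)
        rt <- if (p$name == model$proteins[[1]]$name) 39 else 33
        add(data.frame(
          species = sprintf("%s|Asn%d|%s", p$name, g$position, pr$name),
          protein = p$name, site = g$position, glycan = pr$name,
          peptide = sp$sequence, cterm = NA_character_,
          neutral_mass = pep_mass + pr$mass_bound,
          rt = rt,
          abundance = p$weight * g$occupancy * g$glycoforms$proportion,
          bias = .bias_for(model, pr)))
        if (g$occupancy < 1) {
          add(data.frame(
            species = sprintf("%s|Asn%d|nonglycosylated", p$name, g$position),
            protein = p$name, site = g$position, glycan = NA_character_,
            peptide = sp$sequence, cterm = NA_character_,
            neutral_mass = pep_mass, rt = rt - 8,
            abundance = p$weight * (1 - g$occupancy), bias = 1))
        }
      }
      cv <- p$cterm_variants
      if (nrow(cv) > 1) {
        for (i in seq_len(nrow(cv))) {
          cp <- .cterm_peptide(p, cv$length[i])
          add(data.frame(
            species = sprintf("%s|cterm|%s", p$name, cp$sequence),
            protein = p$name, site = NA_integer_, glycan = NA_character_,
            peptide = cp$sequence, cterm = cv$name[i],
            neutral_mass = peptide_mass(cp$sequence, p$fixed_mods)$monoisotopic,
            rt = 25, abundance = p$weight * cv$prop_peptide[i], bias = 1))
        }
      }
    }
  } else {
    # intact level profiles the purified target protein (first model entry)
    p <- model$proteins[[1]]
    g <- p$glycosites[[1]]
    cv <- p$cterm_variants
    for (i in seq_len(nrow(cv))) {
      vseq <- substr(p$sequence, 1L, cv$length[i])
      n_ox <- sum(p$oxidized_met >= p$offset &
                  p$oxidized_met <= p$offset + cv$length[i] - 1L)
      base_comp <- peptide_composition(vseq) +
        n_ox * c(C = 0, H = 0, N = 0, O = 1, S = 0) -
        p$n_disulfides * c(C = 0, H = 2, N = 0, O = 0, S = 0)
      pr <- .panel_rows(model, g$glycoforms$glycan)
      for (k in seq_len(nrow(pr))) {
        comp <- base_comp + glycan_composition(
          c(hex = pr$hex[k], hexnac = pr$hexnac[k], dhex = pr$dhex[k],
            neuac = pr$neuac[k]), form = "bound")
        add(data.frame(
          species = sprintf("%s|%s|%s%s", p$name, cv$name[i], pr$name[k],
                            if (n_ox > 0) "-ox" else ""),
          protein = p$name, site = g$position, glycan = pr$name[k],
          peptide = NA_character_, cterm = cv$name[i],
          neutral_mass = average_mass(comp),
          rt = 45,
          abundance = cv$prop_intact[i] * g$glycoforms$proportion[k] *
            g$occupancy,
          bias = .bias_for(model, pr[k, , drop = FALSE]),
          composition = I(list(comp))))
      }
      if (g$occupancy < 1) {
        add(data.frame(
          species = sprintf("%s|%s|aglycosylated%s", p$name, cv$name[i],
                            if (n_ox > 0) "-ox" else ""),
          protein = p$name, site = g$position, glycan = NA_character_,
          peptide = NA_character_, cterm = cv$name[i],
          neutral_mass = average_mass(base_comp), rt = 45,
          abundance = cv$prop_intact[i] * (1 - g$occupancy), bias = 1,
          composition = I(list(base_comp))))
      }
    }
  }
  if (length(rows) == 0)
    stop(sprintf("no species observable at the %s level (a glycome of pure %s",
                 level, "PNGase-F-resistant stubs releases nothing)"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one LC-MS run
#'
#' Generates apex features for every ground-truth species at the requested
#' acquisition level: released reduced glycan alditols in negative mode
#' (z = 1-2), chymotryptic (glyco)peptides in positive mode (z = 1-3, with
#' linked CID/ETD fragment spectra), or a positive-mode multi-charge intact
#' protein envelope (z = 15-25, with per-proteoform isotope clusters).
#' Intensities are proportional to abundance x ionization bias x lognormal
#' noise. At the intact level a voltage-dependent fraction of each
#' glycosylated proteoform is lost in-source and appears as a spurious
#' aglycosylated proteoform; the fraction is zero at 200 V.
#'
#' @param model a `ground_truth_model`
#' @param level acquisition level
#' @param seed integer RNG seed; identical seeds give identical runs
#' @param fragmentor_voltage fragmentor potential, V (150-400; only the
#'   intact level is sensitive to it)
#' @return object of class `synthetic_run`: list with `level`, `seed`,
#'   `voltage`, `features` (data.frame: `species`, `protein`, `site`,
#'   `glycan`, `peptide`, `cterm`, `mz`, `z`, `rt`, `intensity`),
#'   `spectra` (glycopeptide level: CID/ETD peak lists) and `clusters`
#'   (intact level: observed isotope clusters per species)
#' @export
simulate_run <- function(model, level = c("glycome", "glycopeptide", "intact"),
                         seed = 1L, fragmentor_voltage = 200) {
  level <- match.arg(level)
  if (fragmentor_voltage < 150 || fragmentor_voltage > 400)
    stop("fragmentor voltage must lie in 150-400 V")
  set.seed(as.integer(seed))
  truth <- ground_truth_species(model, level)
  polarity <- if (level == "glycome") "negative" else "positive"
  clusters <- NULL

  if (level == "intact") {
    f <- insource_decay_fraction(model, fragmentor_voltage)
    if (f > 0) {
      glyco <- !is.na(truth$glycan)
      lost <- truth$abundance[glyco] * f
      truth$abundance[glyco] <- truth$abundance[glyco] - lost
      # the lost population appears as the matching aglycosylated proteoform
      agg <- stats::aggregate(lost, by = list(cterm = truth$cterm[glyco]),
                              FUN = sum)
      p <- model$proteins[[1]]
      cv <- p$cterm_variants
      for (i in seq_len(nrow(agg))) {
        len <- cv$length[match(agg$cterm[i], cv$name)]
        vseq <- substr(p$sequence, 1L, len)
        n_ox <- sum(p$oxidized_met >= p$offset &
                    p$oxidized_met <= p$offset + len - 1L)
        comp <- peptide_composition(vseq) +
          n_ox * c(C = 0, H = 0, N = 0, O = 1, S = 0) -
          p$n_disulfides * c(C = 0, H = 2, N = 0, O = 0, S = 0)
        id <- sprintf("%s|%s|aglycosylated%s", p$name, agg$cterm[i],
                      if (n_ox > 0) "-ox" else "")
        k <- match(id, truth$species)
        if (is.na(k)) {
          truth <- rbind(truth, data.frame(
            species = id, protein = p$name, site = p$glycosites[[1]]$position,
            glycan = NA_character_, peptide = NA_character_,
            cterm = agg$cterm[i], neutral_mass = average_mass(comp), rt = 45,
            abundance = agg$x[i], bias = 1, composition = I(list(comp))))
        } else truth$abundance[k] <- truth$abundance[k] + agg$x[i]
      }
    }
    truth <- truth[truth$abundance > 0, , drop = FALSE]
    clusters <- lapply(seq_len(nrow(truth)), function(i) {
      theo <- isotope_pattern(truth$composition[[i]])
      ab <- theo$abundance *
        (1 + stats::rnorm(nrow(theo), 0, model$noise$isotope_cv))
      ab <- pmax(ab, 0)
      data.frame(mass = theo$mass, abundance = ab / sum(ab))
    })
    names(clusters) <- truth$species
  }

  split <- .charge_split[[level]]
  zs <- as.integer(names(split))
  feats <- list()
  for (i in seq_len(nrow(truth))) {
    base <- truth$abundance[i] * truth$bias[i]
    ints <- base * split * .lognoise(length(split), model$noise$intensity_cv)
    mz <- to_mz(truth$neutral_mass[i], zs, polarity)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, model$noise$mz_ppm * 1e-6))
    feats[[i]] <- data.frame(
      species = truth$species[i], protein = truth$protein[i],
      site = truth$site[i], glycan = truth$glycan[i],
      peptide = truth$peptide[i], cterm = truth$cterm[i],
      mz = mz, z = zs,
      rt = truth$rt[i] + stats::rnorm(length(zs), 0, 0.3),
      intensity = as.numeric(ints))
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  spectra <- NULL
  if (level == "glycopeptide") {
    spectra <- list()
    gp <- truth[!is.na(truth$peptide) & !is.na(truth$glycan), , drop = FALSE]
    for (i in seq_len(nrow(gp))) {
      pr <- .panel_rows(model, gp$glycan[i])
      glycomp <- c(hex = pr$hex, hexnac = pr$hexnac, dhex = pr$dhex,
                   neuac = pr$neuac)
      site_idx <- .site_index_in_peptide(model, gp$protein[i], gp$site[i],
                                         gp$peptide[i])
      prot <- Filter(function(p) p$name == gp$protein[i], model$proteins)[[1]]
      prec_mz <- to_mz(gp$neutral_mass[i], 2L, "positive")
      for (mode in c("CID", "ETD")) {
        frags <- theoretical_fragments(gp$peptide[i], glycan = glycomp,
                                       site_index = site_idx, mode = mode,
                                       max_charge = 2L,
                                       fixed_mods = prot$fixed_mods)
        spectra[[length(spectra) + 1L]] <- list(
          species = gp$species[i], mode = mode, precursor_mz = prec_mz,
          charge = 2L,
          peaks = data.frame(mz = frags$mz,
                             intensity = frags$tier *
                               gp$abundance[i] * gp$bias[i]))
      }
    }
  }

  structure(list(level = level, seed = as.integer(seed),
                 voltage = fragmentor_voltage, features = features,
                 spectra = spectra, clusters = clusters),
            class = "synthetic_run")
}

.site_index_in_peptide <- function(model, protein_name, site, peptide) {
  p <- Filter(function(x) x$name == protein_name, model$proteins)[[1]]
  sp <- .site_peptide(p, site)
  site - sp$start + 1L
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("synthetic %s-level run: %d features, %d species (seed %d, %g V)\n",
              x$level, nrow(x$features), length(unique(x$features$species)),
              x$seed, x$voltage))
  invisible(x)
}

#' Write run features as CSV
#' @param run a `synthetic_run`
#' @param path output file
#' @export
write_feature_csv <- function(run, path) {
  utils::write.csv(run$features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#' @param path CSV file
#' @param level acquisition level of the stored run
#' @export
read_feature_csv <- function(path, level) {
  features <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(level = level, seed = NA_integer_, voltage = NA_real_,
                 features = features, spectra = NULL, clusters = NULL),
            class = "synthetic_run")
}

#' Write fragment spectra in MGF format
#' @param run a glycopeptide-level `synthetic_run`
#' @param path output file
#' @export
write_mgf <- function(run, path) {
  if (is.null(run$spectra)) stop("run carries no fragment spectra")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in run$spectra) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s %s", s$species, s$mode),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read an MGF peak-list file
#' @param path MGF file
#' @return list of spectra (title, precursor_mz, charge, peaks)
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- strsplit(block[kv], "=", fixed = TRUE)
    keys <- vapply(hdr, `[[`, character(1), 1)
    vals <- vapply(hdr, function(x) paste(x[-1], collapse = "="), character(1))
    pk <- do.call(rbind, lapply(strsplit(block[!kv], " +"), as.numeric))
    list(title = vals[keys == "TITLE"],
         precursor_mz = as.numeric(vals[keys == "PEPMASS"]),
         charge = as.integer(sub("\\+$", "", vals[keys == "CHARGE"])),
         peaks = data.frame(mz = pk[, 1], intensity = pk[, 2]))
  })
}
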