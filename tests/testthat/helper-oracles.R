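# Independent oracles and fixture builders used across the suite.

# Brute-force isotopologue enumeration for small molecules: enumerates every
# way of distributing n atoms of each element over its isotopes, multiplies
# multinomial probabilities, and aggregates on nominal-mass offset bins.
# Independent of the package's convolution path.
enumerate_isotopologues <- function(comp) {
  elements <- list(
    C = list(mass = c(12.0000000, 13.0033548), ab = c(0.9893, 0.0107),
             offset = c(0L, 1L)),
    H = list(mass = c(1.0078250, 2.0141018), ab = c(0.999885, 0.000115),
             offset = c(0L, 1L)),
    N = list(mass = c(14.0030740, 15.0001089), ab = c(0.99636, 0.00364),
             offset = c(0L, 1L)),
    O = list(mass = c(15.9949146, 16.9991315, 17.9991604),
             ab = c(0.99757, 0.00038, 0.00205), offset = c(0L, 1L, 2L)),
    S = list(mass = c(31.9720707, 32.9714589, 33.9678669, 35.9670809),
             ab = c(0.9499, 0.0075, 0.0425, 0.0001),
             offset = c(0L, 1L, 2L, 4L)))
  # all count vectors (k_1..k_m) with sum n
  count_vectors <- function(n, m) {
    if (m == 1) return(matrix(n, ncol = 1))
    out <- NULL
    for (k in 0:n) {
      rest <- count_vectors(n - k, m - 1)
      out <- rbind(out, cbind(k, rest))
    }
    out
  }
  per_element <- list()
  for (e in names(comp)) {
    n <- comp[[e]]
    if (is.na(n) || n == 0) next
    el <- elements[[e]]
    cv <- count_vectors(n, length(el$ab))
    prob <- apply(cv, 1, function(k)
      exp(lfactorial(n) - sum(lfactorial(k)) + sum(k * log(el$ab))))
    per_element[[e]] <- data.frame(
      mass = as.numeric(cv %*% el$mass),
      offset = as.integer(cv %*% el$offset),
      prob = prob)
  }
  combo <- Reduce(function(a, b) {
    out <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(mass = a$mass[out$i] + b$mass[out$j],
               offset = a$offset[out$i] + b$offset[out$j],
               prob = a$prob[out$i] * b$prob[out$j])
  }, per_element)
  agg_p <- tapply(combo$prob, combo$offset, sum)
  agg_m <- tapply(combo$prob * combo$mass, combo$offset, sum) / agg_p
  data.frame(mass = as.numeric(agg_m), abundance = as.numeric(agg_p))
}

# minimal one-protein ground-truth model built on the bundled fixture
tiny_model <- function(glycoforms = data.frame(glycan = "GlcNAcb",
                                               proportion = 1),
                       occupancy = 1, noise_cv = 0.05,
                       two_cterm = FALSE) {
  fx <- load_protein_fixtures()
  mature <- substr(fx[["CTSG_SYN"]], 21, 244)
  cv <- if (two_cterm) {
    data.frame(name = c("Arg243", "Ser244"),
               length = c(nchar(mature) - 1L, nchar(mature)),
               prop_peptide = c(0.578, 0.422), prop_intact = c(0.619, 0.381))
  } else {
    data.frame(name = "Arg243", length = nchar(mature) - 1L,
               prop_peptide = 1, prop_intact = 1)
  }
  p <- list(name = "nCG", sequence = mature, offset = 21L, weight = 1,
            cterm_variants = cv,
            glycosites = list(list(position = 71L, occupancy = occupancy,
                                   glycoforms = glycoforms)),
            fixed_mods = character(), oxidized_met = 152L, n_disulfides = 3L)
  m <- ground_truth_model(list(p))
  m$noise$intensity_cv <- noise_cv
  if (noise_cv == 0) {
    m$noise$mz_ppm <- 0
    m$noise$isotope_cv <- 0
  }
  m
}

# synthetic coordinate fixture: four methionine-like residues with planted
# burial ordering (resno 152 exposed, 242 lightly occluded, 35 heavily
# occluded, 110 enclosed by a shell), plus a filler core
planted_met_structure <- function() {
  # with a 5 A probe a neighbour at distance d occludes sample directions
  # within acos((rho^2 + d^2 - R^2) / (2 rho d)) of itself, a wide cone, so
  # partial cages must sit far out (d = 10 A) to leave any surface exposed
  cage <- function(center, dirs, d, resno) {
    data.frame(chain = "A", resno = resno, residue = "ALA", atom = "CB",
               element = "C",
               x = dirs[, 1] * d + center[1], y = dirs[, 2] * d + center[2],
               z = dirs[, 3] * d + center[3], occupancy = 1, radius = 1.7)
  }
  met <- function(resno, center) {
    data.frame(chain = "A", resno = resno, residue = "MET", atom = "SD",
               element = "S", x = center[1], y = center[2], z = center[3],
               occupancy = 1, radius = 1.8)
  }
  pts <- sphere_points(40)
  rbind(
    met(152, c(100, 0, 0)),                    # isolated: fully exposed
    met(242, c(50, 0, 0)),                     # small polar cluster far out
    cage(c(50, 0, 0), pts[pts[, 3] > 0.8, , drop = FALSE], 10, 900),
    met(35, c(-50, 0, 0)),                     # wide cage, narrow exit cone
    cage(c(-50, 0, 0), pts[pts[, 3] > -0.3, , drop = FALSE], 10, 901),
    met(110, c(0, 0, 0)),                      # complete enclosing shell
    cage(c(0, 0, 0), sphere_points(80) * 1, 3, 902))
}

# write a small PDB text from an atom table (fixed-width ATOM records)
write_minimal_pdb <- function(atoms, path, altloc = NULL) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, atoms$atom[i],
            if (!is.null(altloc)) altloc[i] else " ",
            atoms$residue[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], atoms$occupancy[i], 0,
            atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
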