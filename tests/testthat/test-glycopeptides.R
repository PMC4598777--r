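test_that("CID fragments carry the glycan Y-ladder and oxonium ions", {
  fr <- theoretical_fragments("GSNINVTL", glycan = c(hexnac = 1),
                              site_index = 5, mode = "CID", max_charge = 1)
  y0 <- fr$mz[fr$series == "Y" & fr$index == 0]
  y1 <- fr$mz[fr$series == "Y" & fr$index == 1]
  expect_equal(y0, 817.441, tolerance = 1e-3)
  expect_equal(y1, 1020.521, tolerance = 1e-3)
  expect_true(any(abs(fr$mz[fr$series == "B"] - 204.087) < 1e-3))
  # plain peptide: no glycan ladder, only backbone ions
  plain <- theoretical_fragments("GSNINVTL", mode = "CID")
  expect_false(any(plain$series %in% c("Y", "B")))
  expect_true(all(plain$series %in% c("b", "y")))
})

test_that("ETD c/z ions retain the glycan on site-containing fragments", {
  fr <- theoretical_fragments("GSNINVTL", glycan = c(hexnac = 1),
                              site_index = 5, mode = "ETD", max_charge = 1)
  bare <- theoretical_fragments("GSNINVTL", mode = "ETD", max_charge = 1)
  shift <- fr$mz - bare$mz
  contains_site <- ifelse(fr$series == "c", fr$index >= 5,
                          fr$index > nchar("GSNINVTL") - 5)
  expect_equal(shift[contains_site],
               rep(203.079373, sum(contains_site)), tolerance = 1e-5)
  expect_equal(shift[!contains_site], rep(0, sum(!contains_site)),
               tolerance = 1e-9)
})

test_that("complementary c/z pairs reconstruct the precursor", {
  seqs <- c("GSNINVTL", "IRTTMRS", "ACDEFGHIK")
  for (s in seqs) {
    n <- nchar(s)
    prec <- peptide_mass(s)$monoisotopic
    fr <- theoretical_fragments(s, mode = "ETD", max_charge = 1)
    for (i in seq_len(n - 1)) {
      ci <- fr$mz[fr$series == "c" & fr$index == i]
      zi <- fr$mz[fr$series == "z" & fr$index == n - i]
      # singly protonated pair sums to neutral precursor + two protons
      expect_equal(ci + zi, prec + 2 * 1.007276, tolerance = 1e-6)
    }
  }
})

test_that("simulated spectra match their own species, decoys score lower", {
  m <- tiny_model()
  run <- simulate_run(m, "glycopeptide", seed = 41)
  matches <- match_spectra(run$spectra, m)
  cid <- matches[matches$mode == "CID", ]
  etd <- matches[matches$mode == "ETD", ]
  expect_true(all(cid$matched_species == cid$title))
  expect_true(all(cid$n_matched > 0))
  # ETD site bracketing yields a localization verdict
  expect_true(all(etd$localized))
  expect_false(any(cid$localized))
  # a shuffled-sequence decoy explains fewer fragment peaks
  spec <- run$spectra[[which(vapply(run$spectra, `[[`, character(1), "mode")
                             == "CID")[1]]]
  count_matched <- function(theo)
    sum(vapply(theo$mz, function(x) any(abs(spec$peaks$mz - x) <= 0.5),
               logical(1)))
  true_theo <- theoretical_fragments("GSNINVTL", glycan = c(hexnac = 1),
                                     site_index = 5, mode = "CID",
                                     max_charge = 1)
  decoy_theo <- theoretical_fragments("SGINNLTV", glycan = c(hexnac = 1),
                                      site_index = 5, mode = "CID",
                                      max_charge = 1)
  expect_gt(count_matched(true_theo), count_matched(decoy_theo))
})

test_that("site profiling recovers the model distribution", {
  gf <- data.frame(glycan = c("GlcNAcb", "M1", "M2F"),
                   proportion = c(0.6, 0.3, 0.1))
  m0 <- tiny_model(glycoforms = gf, noise_cv = 0)
  prof0 <- site_profile(simulate_run(m0, "glycopeptide", seed = 1), m0)
  expect_equal(stats::setNames(prof0$mean, prof0$species),
               c(GlcNAcb = 60, M1 = 30, M2F = 10), tolerance = 1e-9)
  expect_equal(attr(prof0, "occupancy"), 1)
  # single glycoform: degenerate 100% profile
  m1 <- tiny_model(noise_cv = 0)
  prof1 <- site_profile(simulate_run(m1, "glycopeptide", seed = 1), m1)
  expect_equal(prof1$mean, 100)
  # with default noise, seeded replicates recover within 2 replicate SD
  # (6 replicates: the SD estimate itself needs a few degrees of freedom)
  m <- tiny_model(glycoforms = gf)
  runs <- lapply(42:47, function(s) simulate_run(m, "glycopeptide", seed = s))
  prof <- site_profile(runs, m)
  for (i in seq_len(nrow(prof))) {
    truth <- 100 * gf$proportion[match(prof$species[i], gf$glycan)]
    expect_lt(abs(prof$mean[i] - truth), 2 * prof$sd[i])
  }
})

test_that("occupancy is 100% without a non-glycosylated peptide, else recovered", {
  m_full <- tiny_model(noise_cv = 0)
  run <- simulate_run(m_full, "glycopeptide", seed = 1)
  expect_false(any(grepl("nonglycosylated", run$features$species)))
  expect_equal(attr(site_profile(run, m_full), "occupancy"), 1)
  m_part <- tiny_model(occupancy = 0.8)
  runs <- lapply(51:56, function(s) simulate_run(m_part, "glycopeptide",
                                                 seed = s))
  prof <- site_profile(runs, m_part)
  occ <- attr(prof, "occupancy")
  expect_lt(abs(occ - 0.8), 2 * attr(prof, "occupancy_sd"))
})

test_that("the C-terminal peptide ratio recovers the proteoform proportions", {
  m <- tiny_model(two_cterm = TRUE, noise_cv = 0)
  ct <- cterm_ratio(simulate_run(m, "glycopeptide", seed = 1), m)
  expect_setequal(ct$peptide, c("IRTTMR", "IRTTMRS"))
  expect_equal(ct$mean[ct$peptide == "IRTTMR"], 57.8, tolerance = 1e-9)
  expect_equal(ct$mean[ct$peptide == "IRTTMRS"], 42.2, tolerance = 1e-9)
})
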