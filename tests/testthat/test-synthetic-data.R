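test_that("the default model encodes the published study conditions", {
  m <- default_study_model()
  expect_s3_class(m, "ground_truth_model")
  for (p in m$proteins) {
    expect_equal(sum(p$cterm_variants$prop_peptide), 1, tolerance = 1e-9)
    expect_equal(sum(p$cterm_variants$prop_intact), 1, tolerance = 1e-9)
    for (g in p$glycosites)
      expect_equal(sum(g$glycoforms$proportion), 1, tolerance = 1e-9)
  }
  # fully occupied target site; contaminant sites dominated by M2F
  expect_equal(m$proteins[[1]]$glycosites[[1]]$occupancy, 1.0)
  for (p in m$proteins[-1]) {
    for (g in p$glycosites) {
      top <- g$glycoforms$glycan[which.max(g$glycoforms$proportion)]
      expect_equal(top, "M2F")
    }
  }
  expect_error(ground_truth_model(list(modifyList(
    m$proteins[[1]],
    list(cterm_variants = data.frame(name = "x", length = 200,
                                     prop_peptide = 0.7,
                                     prop_intact = 1))))),
    "sum to 1")
})

test_that("identical seeds give identical runs", {
  m <- default_study_model()
  for (level in c("glycome", "glycopeptide", "intact")) {
    r1 <- simulate_run(m, level, seed = 99)
    r2 <- simulate_run(m, level, seed = 99)
    expect_identical(r1, r2)
    r3 <- simulate_run(m, level, seed = 100)
    expect_false(identical(r1$features$intensity, r3$features$intensity))
  }
})

test_that("zero-noise features sit exactly at theoretical m/z", {
  m <- tiny_model(noise_cv = 0)
  run <- simulate_run(m, "glycopeptide", seed = 1)
  gp_mass <- peptide_mass("GSNINVTL")$monoisotopic +
    glycan_mass(c(hexnac = 1), form = "bound")$monoisotopic
  feats <- run$features[grepl("GlcNAcb", run$features$species), ]
  expect_equal(feats$mz, to_mz(gp_mass, feats$z, "positive"),
               tolerance = 1e-12)
})

test_that("provenance-weighted intensities recover model proportions at zero noise", {
  gf <- data.frame(glycan = c("M1", "M1F", "M2"),
                   proportion = c(0.5, 0.3, 0.2))
  m <- tiny_model(glycoforms = gf, noise_cv = 0)
  run <- simulate_run(m, "glycome", seed = 1)
  shares <- tapply(run$features$intensity, run$features$glycan, sum)
  expect_equal(as.numeric(shares[gf$glycan] / sum(shares)), gf$proportion,
               tolerance = 1e-12)
})

test_that("the glycome level contains only PNGase-F-releasable species", {
  m <- default_study_model()
  run <- simulate_run(m, "glycome", seed = 3)
  expect_false(any(run$features$glycan %in% c("GlcNAcb", "FucGlcNAcb")))
  # contaminants contribute M2F to the released pool
  expect_true("M2F" %in% run$features$glycan)
  expect_true(all(run$features$intensity > 0))
})

test_that("in-source decay is voltage-dependent and absent at 200 V", {
  m <- default_study_model()
  expect_equal(insource_decay_fraction(m, 200), 0)
  expect_equal(insource_decay_fraction(m, 150), 0)
  v <- c(200, 250, 300, 350, 400)
  f <- vapply(v, function(x) insource_decay_fraction(m, x), numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(simulate_run(m, "intact", seed = 1, fragmentor_voltage = 500),
               "150-400")
  mild <- simulate_run(m, "intact", seed = 5, fragmentor_voltage = 200)
  expect_false(any(grepl("aglycosylated", mild$features$species)))
  harsh <- simulate_run(m, "intact", seed = 5, fragmentor_voltage = 350)
  expect_true(any(grepl("aglycosylated", harsh$features$species)))
})

test_that("fragment spectra survive an MGF round trip", {
  m <- tiny_model()
  run <- simulate_run(m, "glycopeptide", seed = 2)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(run, path)
  back <- read_mgf(path)
  expect_equal(length(back), length(run$spectra))
  expect_equal(back[[1]]$precursor_mz, run$spectra[[1]]$precursor_mz,
               tolerance = 1e-6)
  expect_equal(nrow(back[[1]]$peaks), nrow(run$spectra[[1]]$peaks))
})

test_that("feature tables survive a CSV round trip", {
  m <- tiny_model(glycoforms = data.frame(glycan = "M1", proportion = 1))
  run <- simulate_run(m, "glycome", seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(run, path)
  back <- read_feature_csv(path, level = "glycome")
  a <- assign_glycome(back)
  expect_true(any(!is.na(a$isomer_group)))
})
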