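test_that("exact synthetic envelopes deconvolute to the planted mass", {
  M <- 25000
  peaks <- data.frame(mz = to_mz(M, 10:11, "positive"),
                      intensity = c(100, 80))
  dec <- deconvolute(peaks)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$neutral_mass, M, tolerance = 1e-6)
  expect_equal(dec$intensity, 180)
  expect_equal(dec$z_min, 10)
  expect_equal(dec$z_max, 11)
})

test_that("a single peak is insufficient evidence for an envelope", {
  expect_warning(dec <- deconvolute(data.frame(mz = 2501.01, intensity = 1)),
                 "fewer than 2 peaks")
  expect_equal(nrow(dec), 0)
  # two inconsistent peaks: no envelope either
  expect_warning(dec2 <- deconvolute(data.frame(mz = c(900.1, 1333.7),
                                                intensity = c(1, 1))),
                 "no charge envelope")
  expect_equal(nrow(dec2), 0)
})

test_that("deconvolution is scale-invariant and covers z 8-30 envelopes", {
  set.seed(61)
  for (M in c(12000, 25000, 31000)) {
    for (zr in list(8:12, 14:20, 24:30)) {
      peaks <- data.frame(mz = to_mz(M, zr, "positive"),
                          intensity = stats::runif(length(zr), 50, 150))
      d1 <- deconvolute(peaks)
      expect_equal(d1$neutral_mass[which.max(d1$intensity)], M,
                   tolerance = 1e-4)
      scaled <- peaks
      scaled$intensity <- scaled$intensity * 1000
      d2 <- deconvolute(scaled)
      expect_equal(d2$neutral_mass, d1$neutral_mass, tolerance = 1e-9)
    }
  }
})

test_that("harmonic charge assignments are suppressed", {
  M <- 24000
  peaks <- data.frame(mz = to_mz(M, 15:25, "positive"), intensity = 100)
  dec <- deconvolute(peaks)
  # the half-mass harmonic (even charges reinterpreted at half charge)
  # must not survive peak claiming
  expect_equal(nrow(dec), 1)
  expect_equal(dec$neutral_mass, M, tolerance = 1e-6)
})

test_that("simulated intact runs recover the planted proteoform masses", {
  m <- tiny_model(noise_cv = 0, two_cterm = TRUE)
  run <- simulate_run(m, "intact", seed = 1)
  dec <- deconvolute(run$features[, c("mz", "intensity")])
  truth <- ground_truth_species(m, "intact")
  expect_equal(nrow(dec), nrow(truth))
  expect_equal(sort(dec$neutral_mass), sort(truth$neutral_mass),
               tolerance = 1e-6)
})

test_that("proteoform matching annotates +87 and +16 Da partners", {
  m <- tiny_model(two_cterm = TRUE)
  space <- proteoform_space(m)
  expect_true(all(space$oxidized))  # complete Met152 oxidation
  arg <- space[space$id == "nCG|Arg243|GlcNAcb-ox", ]
  ser <- space[space$id == "nCG|Ser244|GlcNAcb-ox", ]
  expect_equal(round(ser$average_mass - arg$average_mass), 87)
  masses <- data.frame(neutral_mass = c(arg$average_mass, ser$average_mass),
                       intensity = c(2, 1))
  mm <- match_proteoforms(masses, space)
  expect_equal(mm$id, c(arg$id, ser$id))
  expect_equal(mm$delta_87_partner, c(ser$id, arg$id))
  # an off-space mass stays unmatched
  off <- match_proteoforms(data.frame(neutral_mass = 30000, intensity = 1),
                           space)
  expect_true(is.na(off$id))
  # an oxidation pair reports +16
  m16 <- data.frame(neutral_mass = c(arg$average_mass,
                                     arg$average_mass + 15.999),
                    intensity = c(1, 1))
  expect_equal(match_proteoforms(m16, space)$delta_16_partner[1],
               match_proteoforms(m16, space)$id[2])
})

test_that("isotope fit is 1 for identity, 0 for disjoint, high for generator output", {
  theo <- isotope_pattern(peptide_composition("GSNINVTL"))
  expect_equal(isotope_fit(theo, theo), 1, tolerance = 1e-12)
  shifted <- theo
  shifted$mass <- shifted$mass + 50
  expect_equal(isotope_fit(shifted, theo), 0)
  expect_error(isotope_fit(theo[0, ], theo), "unresolved")
  m <- default_study_model()
  run <- simulate_run(m, "intact", seed = 62)
  space <- proteoform_space(m)
  for (sp in names(run$clusters)[1:4]) {
    comp <- space$composition[[match(sp, space$id)]]
    fit <- isotope_fit(run$clusters[[sp]], isotope_pattern(comp))
    expect_gt(fit, 0.95)
  }
})

test_that("proteoform quantitation marginals behave", {
  one <- tiny_model(noise_cv = 0)
  q1 <- quantify_proteoforms(simulate_run(one, "intact", seed = 1), one)
  expect_equal(q1$cterm$mean, 100)
  expect_equal(q1$glycoform$mean, 100)
  expect_equal(q1$aglycosylated_fraction, 0)
  # at harsh fragmentor voltage the artefactual aglycosylated form appears
  m <- default_study_model()
  harsh <- quantify_proteoforms(simulate_run(m, "intact", seed = 63,
                                             fragmentor_voltage = 350), m)
  expect_gt(harsh$aglycosylated_fraction, 0)
  mild <- quantify_proteoforms(simulate_run(m, "intact", seed = 63,
                                            fragmentor_voltage = 200), m)
  expect_equal(mild$aglycosylated_fraction, 0)
})
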