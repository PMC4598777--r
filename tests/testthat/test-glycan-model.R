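test_that("the default panel is the 11-structure granule glycome", {
  panel <- default_glycan_panel()
  expect_equal(nrow(panel), 11)
  expect_setequal(
    panel$name,
    c("M0F", "M1", "M1F", "M2", "M2F", "M3F",
      "MA3F-S6", "MA3F-S3", "MA3-S6", "MA2F-S6", "MA2F-S3"))
  # stubs extend the panel for peptide-level work
  with_stubs <- default_glycan_panel(include_stubs = TRUE)
  expect_equal(nrow(with_stubs), 13)
  expect_true(all(c("GlcNAcb", "FucGlcNAcb") %in% with_stubs$name))
  # deterministic (class, mass) ordering
  expect_equal(panel$name, panel[order(match(panel$class,
    c("chitobiose-stub", "paucimannose", "monoantennary-complex")),
    panel$mass_alditol), ]$name)
})

test_that("panel masses are unique except the documented isomer pairs", {
  panel <- default_glycan_panel()
  groups <- split(panel$name, isomer_group(panel))
  multi <- groups[lengths(groups) > 1]
  expect_equal(length(multi), 2)
  expect_setequal(unlist(multi),
                  c("MA3F-S6", "MA3F-S3", "MA2F-S6", "MA2F-S3"))
  # alpha1,3-arm M2/M2F variants are excluded: the single M2/M2F entries
  # carry the alpha1,6 arm
  expect_equal(panel$arm[panel$name %in% c("M2", "M2F")], c("a1,6", "a1,6"))
})

test_that("class composition constraints are enforced", {
  expect_error(glycan_structure("bad", "chitobiose-stub", hex = 1, hexnac = 1),
               "invalid")
  expect_error(glycan_structure("bad", "paucimannose", hex = 4, hexnac = 2),
               "invalid")
  expect_error(glycan_structure("bad", "monoantennary-complex", hex = 4,
                                hexnac = 3, neuac = 1), "sialyl linkage")
  expect_equal(nrow(paucimannose_compositions()), 6)
})

test_that("sialidases respect linkage specificity", {
  panel <- default_glycan_panel()
  s6 <- panel[panel$name == "MA3F-S6", ]
  s3 <- panel[panel$name == "MA3F-S3", ]
  # alpha2,3-specific enzyme leaves alpha2,6 linkages untouched
  expect_equal(apply_exoglycosidase(s6, "a23_sialidase")$neuac, 1)
  expect_equal(apply_exoglycosidase(s3, "a23_sialidase")$neuac, 0)
  # the broad sialidase removes all sialic acids
  digested <- apply_exoglycosidase(panel, "broad_sialidase")
  expect_true(all(digested$neuac == 0))
})

test_that("mannosidase trims terminal alpha-mannoses, never the beta core", {
  panel <- default_glycan_panel(include_stubs = TRUE)
  m2 <- apply_exoglycosidase(panel[panel$name == "M2", ], "jackbean_mannosidase")
  expect_equal(m2$name, "M1")
  m3f <- apply_exoglycosidase(panel[panel$name == "M3F", ],
                              "jackbean_mannosidase")
  expect_equal(m3f$name, "M1F")
  # antenna-substituted arms are not terminal: bimannosyl complex unchanged
  ma2 <- apply_exoglycosidase(panel[panel$name == "MA2F-S6", ],
                              "jackbean_mannosidase")
  expect_equal(ma2$hex, 3)
  # trimannosyl complex loses only the free alpha1,6 arm
  ma3 <- apply_exoglycosidase(panel[panel$name == "MA3F-S6", ],
                              "jackbean_mannosidase")
  expect_equal(ma3$hex, 3)
  # stubs carry nothing cleavable
  stub <- apply_exoglycosidase(panel[panel$name == "GlcNAcb", ],
                               "jackbean_mannosidase")
  expect_equal(stub$hexnac, 1)
})

test_that("exoglycosidase application is idempotent at its fixed point", {
  panel <- default_glycan_panel(include_stubs = TRUE)
  for (enzyme in c("broad_sialidase", "a23_sialidase", "jackbean_mannosidase")) {
    once <- apply_exoglycosidase(panel, enzyme)
    twice <- apply_exoglycosidase(once, enzyme)
    expect_identical(once, twice)
  }
})

test_that("PNGase F releases everything except HexNAc1 stubs", {
  panel <- default_glycan_panel(include_stubs = TRUE)
  released <- pngase_releases(panel)
  expect_false(any(released[panel$name %in% c("GlcNAcb", "FucGlcNAcb")]))
  expect_true(all(released[!panel$name %in% c("GlcNAcb", "FucGlcNAcb")]))
  # M0F keeps an intact chitobiose and is releasable
  expect_true(released[panel$name == "M0F"])
})

test_that("panels survive a CSV round trip", {
  panel <- default_glycan_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_glycan_panel(panel, path)
  back <- read_glycan_panel(path)
  expect_equal(back$name, panel$name)
  expect_equal(back$mass_alditol, panel$mass_alditol, tolerance = 1e-9)
})
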