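test_that("PDB records parse with the altLoc and water policy", {
  atoms <- data.frame(chain = "A", resno = c(1, 1), residue = "ASN",
                      atom = c("CA", "CB"), element = "C",
                      x = c(0, 1.5), y = 0, z = 0, occupancy = 1,
                      radius = 1.7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_minimal_pdb(atoms[1, ], path)
  one <- parse_structure(path)
  expect_equal(nrow(one), 1)
  expect_equal(one$radius, 1.7)
  # alternate locations: the highest-occupancy copy wins
  alt <- rbind(atoms[1, ], atoms[1, ])
  alt$x <- c(0, 9)
  alt$occupancy <- c(0.3, 0.7)
  write_minimal_pdb(alt, path, altloc = c("A", "B"))
  kept <- parse_structure(path)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 9)
  # malformed record reported with its line number
  writeLines(c("ATOM      1  CA ASN A   1", "END"), path)
  expect_error(parse_structure(path), "line 1")
})

test_that("an isolated atom has the closed-form sphere area", {
  atom <- data.frame(resno = 1, residue = "GLY", atom = "CA",
                     x = 0, y = 0, z = 0, radius = 1.7)
  s <- sasa(atom, probe = 5, n_points = 960)
  expect_equal(s$atom_area, 4 * pi * (1.7 + 5)^2, tolerance = 1e-9)
  # two atoms beyond mutual occlusion range are both fully accessible
  two <- rbind(atom, within(atom, x <- 30))
  s2 <- sasa(two, probe = 5)
  expect_equal(s2$atom_area, rep(4 * pi * 6.7^2, 2), tolerance = 1e-9)
})

test_that("an atom enclosed by a neighbour shell has zero accessibility", {
  shell <- sphere_points(80) * 3
  atoms <- data.frame(resno = c(1, rep(2, 80)), residue = "X", atom = "CB",
                      x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                      z = c(0, shell[, 3]), radius = 1.7)
  s <- sasa(atoms, probe = 5, n_points = 960)
  # oracle: brute-force point-in-any-neighbour-sphere test
  pts <- sphere_points(960) * 6.7
  buried <- vapply(seq_len(nrow(pts)), function(i)
    any(colSums((t(shell) - pts[i, ])^2) < 6.7^2), logical(1))
  expect_true(all(buried))
  expect_equal(s$atom_area[1], 0)
})

test_that("SASA converges with sampling density and is rigid-motion invariant", {
  set.seed(81)
  cloud <- data.frame(resno = 1:15, residue = "ALA", atom = "CB",
                      x = stats::rnorm(15, sd = 3),
                      y = stats::rnorm(15, sd = 3),
                      z = stats::rnorm(15, sd = 3), radius = 1.7)
  a960 <- sum(sasa(cloud, probe = 5, n_points = 960)$atom_area)
  a3840 <- sum(sasa(cloud, probe = 5, n_points = 3840)$atom_area)
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
  # rotate + translate
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(cloud[, c("x", "y", "z")]) %*% rot
  moved <- cloud
  moved$x <- xyz[, 1] + 100; moved$y <- xyz[, 2] - 50; moved$z <- xyz[, 3]
  amoved <- sum(sasa(moved, probe = 5, n_points = 960)$atom_area)
  expect_equal(amoved, a960, tolerance = 0.01)
})

test_that("planted methionine burial ordering is recovered", {
  atoms <- planted_met_structure()
  s <- sasa(atoms, probe = 5, n_points = 960)
  met_area <- function(resno) s$residue$area[s$residue$resno == resno]
  # exposed > lightly occluded > caged > enclosed
  expect_gt(met_area(152), met_area(242))
  expect_gt(met_area(242), met_area(35))
  expect_gt(met_area(35), met_area(110))
  expect_equal(met_area(110), 0, tolerance = 1e-9)
})

test_that("site distances follow the declared convention", {
  atoms <- data.frame(chain = "A", resno = c(1, 1, 2), residue = "ASN",
                      atom = c("CA", "CB", "CB"), element = "C",
                      x = c(10, 0, 3), y = c(10, 0, 4), z = 0,
                      occupancy = 1, radius = 1.7)
  d <- site_distance(atoms, 1, 2)
  expect_equal(as.numeric(d), 5)  # 3-4-5 from the side-chain atom only
  expect_equal(attr(d, "convention"), "sidechain-min")
  expect_equal(as.numeric(site_distance(atoms, 1, 1)), 0)
  expect_error(site_distance(atoms, 99, 2), "absent")
})
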