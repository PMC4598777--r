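## Structural context of a glycosite: PDB parsing, solvent-accessible
## surface area with a large (5 A) probe, and site-to-active-site distances.
##
## The SASA implementation is Shrake-Rupley: per atom, the fraction of
## quasi-uniform sphere sample points at radius (r_vdw + probe) not buried
## inside any neighbour's expanded sphere, times the sphere area. With a
## 5 A probe the quantity ranks residue exposure the way large-probe
## accessibility scores do; absolute values depend on the radii table
## (Bondi van der Waals radii are bundled) and are reported in A^2.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

#' Parse a PDB structure file
#'
#' Delegates parsing to [bio3d::read.pdb()], then applies the module's
#' record policy: waters and hetero groups are excluded by default, and
#' alternate locations are resolved to the highest-occupancy copy. Bondi
#' van der Waals radii are attached per atom (element inferred from the
#' atom record).
#'
#' @param path PDB file path
#' @param keep_hetero keep HETATM records (waters are always dropped)
#' @return data.frame of atom records: `chain`, `resno`, `residue`, `atom`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `radius`
#' @export
parse_structure <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d", bad[1]))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("PDB parsing failed: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$resid != "HOH", ]
  if (!keep_hetero) at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no atom records retained")
  # resolve alternate locations to the highest-occupancy copy
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      idx[which.max(at$o[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), ]
  }
  element <- at$elesy
  missing <- is.na(element) | element == ""
  element[missing] <- substr(trimws(at$elety[missing]), 1, 1)
  radius <- .vdw_radii[element]
  radius[is.na(radius)] <- .vdw_default
  data.frame(chain = at$chain, resno = at$resno, residue = at$resid,
             atom = trimws(at$elety), element = element,
             x = at$x, y = at$y, z = at$z,
             occupancy = ifelse(is.na(at$o), 1, at$o), radius = radius,
             row.names = NULL)
}

#' Quasi-uniform points on the unit sphere (golden-section spiral)
#' @param n number of points (>= 100 for SASA use)
#' @return n x 3 matrix
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param atoms atom table from [parse_structure()] (or any data.frame with
#'   `x`, `y`, `z`, `radius`, and optionally `resno`/`residue`)
#' @param probe probe radius, A (5.0: the large-probe accessibility
#'   convention used to rank glycosite and methionine exposure)
#' @param n_points sphere sample points per atom (>= 100)
#' @return list with `atom_area` (A^2 per atom) and `residue` (data.frame
#'   `resno`, `residue`, `area`), plus the config used
#' @export
sasa <- function(atoms, probe = 5.0, n_points = 960L) {
  if (nrow(atoms) < 1) stop("at least one atom is required")
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("use at least 100 sphere sample points")
  pts <- sphere_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r_exp <- atoms$radius + probe
  n <- nrow(atoms)
  area <- numeric(n)
  # neighbour search cutoff: two largest expanded radii
  max_r <- max(r_exp)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r_exp[i] + max_r)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r_exp[i] + r_exp[nb])^2]
    sp <- sweep(pts * r_exp[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        d2j <- colSums((t(sp[!buried, , drop = FALSE]) - xyz[j, ])^2)
        hit <- d2j < r_exp[j]^2
        buried[!buried][hit] <- TRUE
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * r_exp[i]^2 * acc / n_points
  }
  out <- list(atom_area = area, probe = probe, n_points = n_points)
  if (!is.null(atoms$resno)) {
    res <- stats::aggregate(area, by = list(resno = atoms$resno), FUN = sum)
    names(res)[2] <- "area"
    if (!is.null(atoms$residue))
      res$residue <- atoms$residue[match(res$resno, atoms$resno)]
    out$residue <- res
  }
  out
}

.sidechain_exclude <- c("N", "CA", "C", "O", "OXT")

#' Distance between a residue and a residue set
#'
#' Default convention: minimum distance between the heavy side-chain atoms
#' of residue `a` and any atom of the residues in `b`. The convention used
#' is attached to the result, since published distances rarely state
#' theirs.
#'
#' @param atoms atom table from [parse_structure()]
#' @param a residue number of the query residue
#' @param b integer vector of residue numbers (e.g. a catalytic triad)
#' @param convention `"sidechain-min"` or `"all-atom-min"`
#' @return distance in A with attribute `convention`
#' @export
site_distance <- function(atoms, a, b,
                          convention = c("sidechain-min", "all-atom-min")) {
  convention <- match.arg(convention)
  qa <- atoms[atoms$resno == a, ]
  if (convention == "sidechain-min") {
    sc <- qa[!qa$atom %in% .sidechain_exclude & qa$element != "H", ]
    if (nrow(sc) > 0) qa <- sc
  }
  qb <- atoms[atoms$resno %in% b, ]
  if (nrow(qa) == 0) stop("residue ", a, " absent from structure")
  if (nrow(qb) == 0) stop("residue set {", paste(b, collapse = ","),
                          "} absent from structure")
  d <- sqrt(outer(qa$x, qb$x, `-`)^2 + outer(qa$y, qb$y, `-`)^2 +
            outer(qa$z, qb$z, `-`)^2)
  structure(min(d), convention = convention)
}
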