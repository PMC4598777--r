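## The constrained N-glycan structure space of azurophilic-granule
## glycoproteins, and its enzymatic transformation rules.
##
## Structures are modelled as monosaccharide composition plus flat linkage
## annotations (core fucose, mannose arm, sialyl linkage) rather than full
## trees: mass, retention class and exoglycosidase response are the only
## discriminating evidence consumed downstream, and none requires deeper
## topology. Three classes are covered:
##
##  * chitobiose-stub:       HexNAc 1-2, Hex 0           (GlcNAcb, Fuca1,6GlcNAcb, M0F)
##  * paucimannose:          HexNAc 2,   Hex 1-3, no NeuAc (M1..M3F)
##  * monoantennary-complex: HexNAc 3,   Hex 3-4, NeuAc 0-1
##
## Core fucosylation (dHex 0-1) is allowed everywhere.

.glycan_classes <- c("chitobiose-stub", "paucimannose", "monoantennary-complex")

#' Construct a glycan structure
#'
#' @param name short name (e.g. `"M2F"`, `"GlcNAcb"`)
#' @param class one of `"chitobiose-stub"`, `"paucimannose"`,
#'   `"monoantennary-complex"`
#' @param hex,hexnac,dhex,neuac monosaccharide counts
#' @param arm mannose-arm linkage for the single arm of bimannosyl species
#'   (`"a1,3"`, `"a1,6"` or `NA`)
#' @param sialyl sialyl linkage (`"a2,3"`, `"a2,6"` or `NA`)
#' @return one-row data.frame of class `glycan_panel`
#' @export
glycan_structure <- function(name, class, hex = 0, hexnac = 0, dhex = 0,
                             neuac = 0, arm = NA_character_,
                             sialyl = NA_character_) {
  class <- match.arg(class, .glycan_classes)
  ok <- switch(class,
    "chitobiose-stub" = hexnac %in% 1:2 && hex == 0 && neuac == 0,
    "paucimannose" = hexnac == 2 && hex %in% 1:3 && neuac == 0,
    "monoantennary-complex" = hexnac == 3 && hex %in% 3:4 && neuac %in% 0:1)
  if (!ok || !dhex %in% 0:1)
    stop(sprintf("composition Hex%d HexNAc%d dHex%d NeuAc%d invalid for class %s",
                 hex, hexnac, dhex, neuac, class))
  if (neuac > 0 && is.na(sialyl))
    stop("sialylated structure needs a sialyl linkage annotation")
  comp <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  out <- data.frame(
    name = name, class = class, hex = hex, hexnac = hexnac, dhex = dhex,
    neuac = neuac, core_fucose = dhex > 0, arm = arm, sialyl = sialyl,
    zic_hilic_retained = neuac > 0,
    mass_alditol = glycan_mass(comp, "reduced-alditol")$monoisotopic,
    mass_bound = glycan_mass(comp, "bound")$monoisotopic,
    stringsAsFactors = FALSE)
  class(out) <- c("glycan_panel", "data.frame")
  out
}

#' The default neutrophil glycan panel
#'
#' With defaults this is the 11-structure released glycome of azurophilic
#' granule proteins: the chitobiose-core M0F, the five paucimannosidic
#' structures M1/M1F/M2/M2F/M3F (alpha1,3-arm isomers of M2/M2F are absent
#' in human neutrophils and excluded), and five monoantennary monosialylated
#' complex structures (tri-/bimannosyl core, with/without core fucose,
#' alpha2,3/alpha2,6 sialylation). `include_stubs = TRUE` adds the two
#' PNGase-F-resistant Asn-linked stubs GlcNAcb and Fuca1,6GlcNAcb used for
#' peptide-level work.
#'
#' @param include_stubs add the HexNAc1(dHex0-1) stubs
#' @param classes classes to include
#' @return `glycan_panel` data.frame, ordered by (class, mass)
#' @export
default_glycan_panel <- function(include_stubs = FALSE,
                                 classes = .glycan_classes) {
  rows <- list(
    glycan_structure("M0F", "chitobiose-stub", hexnac = 2, dhex = 1),
    glycan_structure("M1",  "paucimannose", hex = 1, hexnac = 2),
    glycan_structure("M1F", "paucimannose", hex = 1, hexnac = 2, dhex = 1),
    glycan_structure("M2",  "paucimannose", hex = 2, hexnac = 2, arm = "a1,6"),
    glycan_structure("M2F", "paucimannose", hex = 2, hexnac = 2, dhex = 1,
                     arm = "a1,6"),
    glycan_structure("M3F", "paucimannose", hex = 3, hexnac = 2, dhex = 1),
    glycan_structure("MA3F-S6", "monoantennary-complex", hex = 4, hexnac = 3,
                     dhex = 1, neuac = 1, sialyl = "a2,6"),
    glycan_structure("MA3F-S3", "monoantennary-complex", hex = 4, hexnac = 3,
                     dhex = 1, neuac = 1, sialyl = "a2,3"),
    glycan_structure("MA3-S6", "monoantennary-complex", hex = 4, hexnac = 3,
                     neuac = 1, sialyl = "a2,6"),
    glycan_structure("MA2F-S6", "monoantennary-complex", hex = 3, hexnac = 3,
                     dhex = 1, neuac = 1, sialyl = "a2,6"),
    glycan_structure("MA2F-S3", "monoantennary-complex", hex = 3, hexnac = 3,
                     dhex = 1, neuac = 1, sialyl = "a2,3"))
  if (include_stubs) {
    rows <- c(list(
      glycan_structure("GlcNAcb", "chitobiose-stub", hexnac = 1),
      glycan_structure("FucGlcNAcb", "chitobiose-stub", hexnac = 1, dhex = 1)),
      rows)
  }
  panel <- do.call(rbind, rows)
  panel <- panel[panel$class %in% classes, , drop = FALSE]
  panel <- panel[order(match(panel$class, .glycan_classes),
                       panel$mass_alditol), ]
  rownames(panel) <- NULL
  class(panel) <- c("glycan_panel", "data.frame")
  panel
}

#' Paucimannose composition grid
#'
#' All Hex1-3 HexNAc2 dHex0-1 compositions (6 in total).
#' @return data.frame with columns `hex`, `hexnac`, `dhex`
#' @export
paucimannose_compositions <- function() {
  grid <- expand.grid(hex = 1:3, dhex = 0:1)
  data.frame(hex = grid$hex, hexnac = 2L, dhex = grid$dhex)
}

#' Apply an exoglycosidase to panel structures
#'
#' Implements the three trimming enzymes used for linkage assignment:
#' the linkage-unspecific sialidase removes all NeuAc, the alpha2,3-specific
#' sialidase removes NeuAc only from alpha2,3-linked structures, and the
#' alpha1,2/3 > alpha1,6-preferring jack bean alpha-mannosidase removes
#' terminal alpha-linked mannoses exhaustively (the beta-mannose is never
#' removed; antenna-substituted arms are not terminal). Application is a
#' no-op when nothing is cleavable, and idempotent.
#'
#' @param panel a `glycan_panel` (one or more rows)
#' @param enzyme `"broad_sialidase"`, `"a23_sialidase"` or
#'   `"jackbean_mannosidase"`
#' @return the transformed panel
#' @export
apply_exoglycosidase <- function(panel,
                                 enzyme = c("broad_sialidase", "a23_sialidase",
                                            "jackbean_mannosidase")) {
  enzyme <- match.arg(enzyme)
  out <- panel
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (enzyme == "broad_sialidase" && r$neuac > 0) {
      r$neuac <- 0L; r$sialyl <- NA_character_
    } else if (enzyme == "a23_sialidase" && r$neuac > 0 &&
               identical(r$sialyl, "a2,3")) {
      r$neuac <- 0L; r$sialyl <- NA_character_
    } else if (enzyme == "jackbean_mannosidase") {
      if (r$class == "paucimannose" && r$hex > 1) {
        # all alpha-mannoses are terminal: exhaustive digest down to Man-beta
        r$hex <- 1L; r$arm <- NA_character_
      } else if (r$class == "monoantennary-complex" && r$hex == 4) {
        # trimannosyl core: the antenna-free alpha1,6 arm is terminal
        r$hex <- 3L
      }
    }
    r$core_fucose <- r$dhex > 0
    r$zic_hilic_retained <- r$neuac > 0
    comp <- c(hex = r$hex, hexnac = r$hexnac, dhex = r$dhex, neuac = r$neuac)
    r$mass_alditol <- glycan_mass(comp, "reduced-alditol")$monoisotopic
    r$mass_bound <- glycan_mass(comp, "bound")$monoisotopic
    r$name <- .canonical_glycan_name(r)
    out[i, ] <- r
  }
  out
}

.canonical_glycan_name <- function(r) {
  ref <- default_glycan_panel(include_stubs = TRUE)
  hit <- ref[ref$hex == r$hex & ref$hexnac == r$hexnac & ref$dhex == r$dhex &
             ref$neuac == r$neuac &
             (is.na(ref$sialyl) == is.na(r$sialyl)) &
             (is.na(ref$sialyl) | ref$sialyl %in% r$sialyl), , drop = FALSE]
  if (nrow(hit) == 1) hit$name else
    sprintf("Hex%d HexNAc%d dHex%d NeuAc%d", r$hex, r$hexnac, r$dhex, r$neuac)
}

#' Is a glycan released from its peptide carrier by PNGase F?
#'
#' Asn-linked HexNAc1 stubs (GlcNAcb, Fuca1,6GlcNAcb) resist PNGase F;
#' everything with an intact chitobiose core (HexNAc >= 2 at the core) is
#' released.
#'
#' @param panel a `glycan_panel`
#' @return logical vector, one per row
#' @export
pngase_releases <- function(panel) {
  !(panel$class == "chitobiose-stub" & panel$hexnac == 1)
}

#' Isomer groups of a panel
#'
#' Structures sharing a monosaccharide composition cannot be separated by
#' mass alone; the assignment stage therefore reports isomer groups.
#'
#' @param panel a `glycan_panel`
#' @return character vector of composition keys, one per row
#' @export
isomer_group <- function(panel) {
  sprintf("Hex%d.HexNAc%d.dHex%d.NeuAc%d",
          panel$hex, panel$hexnac, panel$dhex, panel$neuac)
}

#' Write / read a glycan panel as CSV
#' @param panel a `glycan_panel`
#' @param path file path
#' @export
write_glycan_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_glycan_panel
#' @export
read_glycan_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(panel) <- c("glycan_panel", "data.frame")
  panel
}
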