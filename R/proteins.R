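## Protein fixtures and in-silico chymotryptic digestion.

#' Load the bundled synthetic granule-protein fixtures
#'
#' The package ships synthetic stand-in sequences for the three co-purified
#' neutrophil granule proteins (a cathepsin G-like protease, an
#' azurocidin-like and an elastase-like chain). They are not the natural
#' sequences: they are constructed so that every positional constraint the
#' analysis depends on holds (the single Asn71 sequon inside the chymotryptic
#' peptide GSNINVTL, the C-terminal 238-IRTTMR(S)-244 peptides, Met152,
#' active-site His64/Asp108/Ser201, six cysteines, and the contaminant
#' glycosites Asn126/Asn171 and Asn124/Asn173).
#'
#' @param path FASTA file; defaults to the bundled fixture
#' @return named character vector of sequences
#' @export
load_protein_fixtures <- function(path = system.file(
    "extdata", "synthetic_granule_proteins.fasta", package = "glycotriad")) {
  if (!nzchar(path) || !file.exists(path))
    stop("protein fixture FASTA not found; reinstall the package or pass a path")
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), " "), `[[`, character(1), 1)
  out
}

#' Find N-glycosylation sequons
#'
#' N-X-S/T with X != P, positions reported in the supplied numbering offset.
#'
#' @param sequence amino-acid string
#' @param offset unprocessed-chain position of residue 1 of `sequence`
#' @return integer vector of Asn positions
#' @export
find_sequons <- function(sequence, offset = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 3) return(integer())
  idx <- which(aa[seq_len(n - 2)] == "N" &
               aa[seq_len(n - 2) + 1L] != "P" &
               aa[seq_len(n - 2) + 2L] %in% c("S", "T"))
  idx + offset - 1L
}

.chymo_residues <- c("F", "Y", "W", "L", "M")

#' In-silico chymotryptic digestion
#'
#' Chymotrypsin cleaves C-terminal to F, Y, W, L and M, never before Pro
#' (His cleavage is excluded: the observed peptide repertoire requires L/M
#' specificity and is inconsistent with additional H cleavage). The protein
#' C-terminus is always a valid peptide terminus. In `"semi"` mode one
#' terminus may be non-canonical (sub-peptides of fully specific peptides,
#' minimum length `min_length`).
#'
#' @param sequence protein (or mature-chain) amino-acid string
#' @param missed_cleavages maximum internal missed cleavage sites
#' @param specificity `"full"` or `"semi"`
#' @param protein protein identifier carried into the output
#' @param offset unprocessed-chain position of residue 1 of `sequence`
#' @param min_length minimum peptide length reported
#' @return data.frame of peptide species: `protein`, `sequence`, `start`,
#'   `end` (1-based inclusive, in `offset` numbering), `missed`, `semi`,
#'   `glycosite` (Asn position or NA)
#' @export
digest <- function(sequence, missed_cleavages = 0L,
                   specificity = c("full", "semi"), protein = "protein",
                   offset = 1L, min_length = 4L) {
  specificity <- match.arg(specificity)
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  sites <- which(aa %in% .chymo_residues)
  sites <- sites[sites < n]
  sites <- sites[aa[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  segs <- data.frame(start = utils::head(bounds, -1) + 1L, end = bounds[-1])
  peps <- list()
  for (i in seq_len(nrow(segs))) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nrow(segs)) break
      peps[[length(peps) + 1L]] <- data.frame(
        start = segs$start[i], end = segs$end[j], missed = m, semi = FALSE)
    }
  }
  peps <- do.call(rbind, peps)
  if (specificity == "semi") {
    extra <- list()
    for (i in seq_len(nrow(peps))) {
      s <- peps$start[i]; e <- peps$end[i]
      len <- e - s + 1L
      if (len <= min_length) next
      for (k in (s + min_length - 1L):(e - 1L))   # ragged C-terminus
        extra[[length(extra) + 1L]] <- data.frame(
          start = s, end = k, missed = peps$missed[i], semi = TRUE)
      for (k in (s + 1L):(e - min_length + 1L))   # ragged N-terminus
        extra[[length(extra) + 1L]] <- data.frame(
          start = k, end = e, missed = peps$missed[i], semi = TRUE)
    }
    if (length(extra)) peps <- rbind(peps, do.call(rbind, extra))
  }
  peps <- peps[peps$end - peps$start + 1L >= min_length | !peps$semi, ]
  peps$sequence <- vapply(seq_len(nrow(peps)), function(i)
    substr(sequence, peps$start[i], peps$end[i]), character(1))
  peps <- peps[!duplicated(peps[c("start", "end")]), ]
  peps$start <- peps$start + offset - 1L
  peps$end <- peps$end + offset - 1L
  sequons <- find_sequons(sequence, offset)
  peps$glycosite <- vapply(seq_len(nrow(peps)), function(i) {
    hit <- sequons[sequons >= peps$start[i] & sequons <= peps$end[i]]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  peps$protein <- protein
  rownames(peps) <- NULL
  peps[c("protein", "sequence", "start", "end", "missed", "semi", "glycosite")]
}
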