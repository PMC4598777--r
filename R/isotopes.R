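## Aggregated (nominal-mass) isotopic distributions by iterated convolution
## of the per-element natural-abundance distributions.
##
## The pattern of n atoms of one element is obtained by binary-exponentiation
## convolution of the single-atom distribution; element patterns are then
## convolved together. Peaks are aggregated on nominal-mass bins (~1.0034 Da
## spacing), which is the resolution at which a QTOF resolves isotopologues
## of an intact protein. Fine structure is deliberately not modelled.

# distribution representation: list(ab = abundance by offset 0..K,
# wm = abundance-weighted mass sum by offset)
.dist_one <- function(element) {
  e <- .elements[[element]]
  K <- max(e$offset)
  ab <- numeric(K + 1L)
  wm <- numeric(K + 1L)
  ab[e$offset + 1L] <- e$ab
  wm[e$offset + 1L] <- e$ab * e$mass
  list(ab = ab, wm = wm)
}

.dist_conv <- function(a, b, prune = 1e-12) {
  na <- length(a$ab); nb <- length(b$ab)
  ab <- numeric(na + nb - 1L)
  wm <- numeric(na + nb - 1L)
  ma <- ifelse(a$ab > 0, a$wm / pmax(a$ab, .Machine$double.xmin), 0)
  for (i in seq_len(na)) {
    if (a$ab[i] == 0) next
    idx <- i:(i + nb - 1L)
    ab[idx] <- ab[idx] + a$ab[i] * b$ab
    wm[idx] <- wm[idx] + a$ab[i] * (b$wm + b$ab * ma[i])
  }
  keep <- ab > prune
  if (any(keep)) {
    last <- max(which(keep))
    ab <- ab[seq_len(last)]
    wm <- wm[seq_len(last)]
  }
  list(ab = ab, wm = wm)
}

.dist_power <- function(d, n) {
  stopifnot(n >= 1)
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1)
      result <- if (is.null(result)) base else .dist_conv(result, base)
    n <- n %/% 2
    if (n > 0) base <- .dist_conv(base, base)
  }
  result
}

#' Aggregated isotopic distribution of an elemental composition
#'
#' Computes the theoretical isotope pattern by convolving natural-abundance
#' distributions, aggregated on nominal-mass bins. The returned peaks are
#' truncated once their cumulative abundance reaches `coverage` and
#' renormalized to sum to 1.
#'
#' @param comp named CHNOS count vector (e.g. from [peptide_composition()])
#' @param coverage cumulative abundance retained before truncation
#' @return data.frame of class `isotope_pattern` with columns `mass` (Da,
#'   abundance-weighted mean per bin) and `abundance` (sums to 1)
#' @examples
#' isotope_pattern(peptide_composition("GSNINVTL"))
#' @export
isotope_pattern <- function(comp, coverage = 0.9999) {
  comp <- .as_comp(comp)
  if (sum(comp) < 1) stop("composition must contain at least one atom")
  dists <- lapply(names(comp)[comp > 0],
                  function(e) .dist_power(.dist_one(e), comp[[e]]))
  d <- Reduce(.dist_conv, dists)
  ab <- d$ab
  mass <- ifelse(ab > 0, d$wm / pmax(ab, .Machine$double.xmin), NA_real_)
  keep <- ab > 0
  ab <- ab[keep]; mass <- mass[keep]
  ord <- order(mass)
  ab <- ab[ord]; mass <- mass[ord]
  # truncate at the requested cumulative coverage, keeping most-abundant bins
  ord_ab <- order(ab, decreasing = TRUE)
  n_keep <- which(cumsum(ab[ord_ab]) >= coverage)[1]
  if (is.na(n_keep)) n_keep <- length(ab)
  keep <- sort(ord_ab[seq_len(n_keep)])
  ab <- ab[keep]; mass <- mass[keep]
  out <- data.frame(mass = mass, abundance = ab / sum(ab))
  class(out) <- c("isotope_pattern", "data.frame")
  out
}
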