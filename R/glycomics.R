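## Released-glycan (glycome) stage: composition assignment of negative-mode
## alditol features and relative EIC quantitation.

#' Assign released-glycan features to panel isomer groups
#'
#' Deprotonated-species arithmetic ([M-H]-, [M-2H]2-) at the feature's
#' charge. A feature is matched to the unique isomer group (structures
#' sharing a composition) whose alditol mass lies within `tol_da`; features
#' matching more than one composition within tolerance are flagged
#' ambiguous, features matching none are left unassigned.
#'
#' @param run a glycome-level `synthetic_run` (or feature table read with
#'   [read_feature_csv()])
#' @param panel a `glycan_panel` (release panel, no stubs)
#' @param tol_da mass tolerance, Da (unit-resolution ion trap default)
#' @return feature table with `isomer_group`, `group_members`,
#'   `mass_error_da`, `mass_error_ppm`, `ambiguous` columns
#' @export
assign_glycome <- function(run, panel = default_glycan_panel(),
                           tol_da = 0.15) {
  if (run$level != "glycome") stop("run level must be 'glycome'")
  if (tol_da <= 0) stop("tolerance must be positive")
  groups <- isomer_group(panel)
  comp <- !duplicated(groups)
  comp_mass <- panel$mass_alditol[comp]
  comp_key <- groups[comp]
  members <- vapply(comp_key, function(k)
    paste(panel$name[groups == k], collapse = "/"), character(1))
  feats <- run$features
  feats$isomer_group <- NA_character_
  feats$group_members <- NA_character_
  feats$mass_error_da <- NA_real_
  feats$mass_error_ppm <- NA_real_
  feats$ambiguous <- FALSE
  for (i in seq_len(nrow(feats))) {
    obs_mass <- mass_from_mz(feats$mz[i], feats$z[i], "negative")
    err <- obs_mass - comp_mass
    hit <- which(abs(err) <= tol_da)
    if (length(hit) == 0) next
    best <- hit[which.min(abs(err[hit]))]
    feats$isomer_group[i] <- comp_key[best]
    feats$group_members[i] <- members[best]
    feats$mass_error_da[i] <- err[best]
    feats$mass_error_ppm[i] <- 1e6 * err[best] / comp_mass[best]
    feats$ambiguous[i] <- length(hit) > 1
  }
  feats
}

#' Relative glycome quantitation from EIC areas
#'
#' Per isomer group, sums EIC areas over all observed charge states and
#' divides by the grand total of all assigned glycan areas; with several
#' replicate assignment tables, mean +/- SD.
#'
#' @param assignments one assignment table from [assign_glycome()], or a
#'   list of replicate tables
#' @param trace_threshold relative abundance (%) below which an entry is
#'   flagged trace
#' @return `quant_profile` data.frame: `species` (isomer-group key),
#'   `members`, `mean` (%), `sd`, `trace`
#' @export
quantify_glycome <- function(assignments, trace_threshold = 0.5) {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  per_rep <- lapply(assignments, function(a) {
    a <- a[!is.na(a$isomer_group), ]
    if (nrow(a) == 0) stop("no assigned glycan features")
    shares <- tapply(a$intensity, a$isomer_group, sum)
    list(shares = 100 * shares / sum(shares),
         members = tapply(a$group_members, a$isomer_group, `[`, 1))
  })
  keys <- sort(unique(unlist(lapply(per_rep, function(x) names(x$shares)))))
  mat <- sapply(per_rep, function(x) {
    v <- stats::setNames(numeric(length(keys)), keys)
    v[names(x$shares)] <- x$shares
    v
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(keys))
  members <- stats::setNames(rep(NA_character_, length(keys)), keys)
  for (x in per_rep) members[names(x$members)] <- unlist(x$members)
  prof <- data.frame(species = keys, members = unname(members),
                     mean = rowMeans(mat), sd = apply(mat, 1, stats::sd))
  prof$trace <- prof$mean < trace_threshold
  prof <- prof[order(-prof$mean), ]
  rownames(prof) <- NULL
  class(prof) <- c("quant_profile", "data.frame")
  prof
}

#' Count distinct structures represented in a glycome assignment
#'
#' Distinct structures across all assigned isomer groups (each group counts
#' all of its annotated members, since mass cannot separate them).
#'
#' @param assignments table from [assign_glycome()]
#' @return integer count
#' @export
count_assigned_structures <- function(assignments) {
  groups <- unique(assignments$group_members[!is.na(assignments$group_members)])
  length(unique(unlist(strsplit(groups, "/", fixed = TRUE))))
}
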