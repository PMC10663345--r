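rel_abund <- function(table) {
  m <- unclass(table)
  totals <- rowSums(m)
  if (any(totals <= 0))
    abort(paste0("Zero-total sample '",
                 rownames(m)[which(totals <= 0)[1]],
                 "' has no relative abundances."))
  m / totals
}

#' Core-microbiome membership rules
#'
#' Three complementary definitions of the plant-endophyte core community.
#' `core_a()` is a global rule: an ASV belongs when it reaches at least
#' `min_rel_abund` (default 0.5%) within-sample relative abundance in at
#' least `min_samples` (default 4) samples anywhere in the data set.
#' `core_b()` is tissue-and-stage aware: samples are partitioned into
#' tissue-by-stage subsets, and an ASV belongs when in at least one subset
#' it reaches `min_rel_abund` (default 1%) in at least `min_prevalence`
#' (default 20%) of the subset's samples. All thresholds are inclusive.
#'
#' @param table [asv_table] with positive per-sample totals (relative
#'   abundance is computed against the current, post-quality-filter
#'   totals).
#' @param min_rel_abund,min_samples,min_prevalence Rule thresholds.
#' @return Character vector of retained ASV identifiers.
#' @export
core_a <- function(table, min_rel_abund = 0.005, min_samples = 4) {
  ra <- rel_abund(table)
  hits <- colSums(ra >= min_rel_abund)
  colnames(ra)[hits >= min_samples]
}

#' @rdname core_a
#' @param metadata Sample metadata assigning each table sample a tissue and
#'   stage.
#' @export
core_b <- function(table, metadata, min_rel_abund = 0.01,
                   min_prevalence = 0.2) {
  al <- align_samples(table, metadata)
  ra <- rel_abund(al$table)
  subset_key <- paste(al$metadata$tissue, al$metadata$stage, sep = ":")
  keep <- rep(FALSE, ncol(ra))
  for (key in unique(subset_key)) {
    idx <- subset_key == key
    if (!any(idx)) next
    prev <- colSums(ra[idx, , drop = FALSE] >= min_rel_abund) / sum(idx)
    keep <- keep | (prev >= min_prevalence)
  }
  colnames(ra)[keep]
}

# all distinct reassignments of group labels preserving group sizes,
# as an n x n_perm matrix of index permutations (identity first)
enumerate_group_permutations <- function(groups) {
  n <- length(groups)
  if (n > 10) abort("Exhaustive enumeration limited to n <= 10.")
  perms <- list(seq_len(n))
  # all permutations of 1..n via recursion, then deduplicate by label map
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perm(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ap <- all_perm(seq_len(n))
  seen <- new.env(hash = TRUE)
  keep <- list()
  for (p in ap) {
    key <- paste(groups[p], collapse = "\r")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    keep[[length(keep) + 1]] <- p
  }
  do.call(cbind, keep)
}

indval_stats <- function(m, groups, specificity = "mean") {
  glev <- sort(unique(groups))
  fmean <- if (specificity == "mean") colMeans else colSums
  means <- sapply(glev, function(g)
    fmean(m[groups == g, , drop = FALSE]))             # K x G
  pres <- sapply(glev, function(g)
    colMeans(m[groups == g, , drop = FALSE] > 0))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); pres <- matrix(pres, nrow = 1)
  }
  tot <- rowSums(means)
  A <- means / ifelse(tot > 0, tot, NA_real_)
  iv <- sqrt(A * pres)
  stat <- apply(iv, 1, function(z) if (all(is.na(z))) NA_real_ else
    max(z, na.rm = TRUE))
  best <- apply(iv, 1, function(z) if (all(is.na(z))) NA_character_ else
    glev[which.max(z)])
  list(stat = stat, best = best, indval = iv, groups = glev)
}

#' Indicator-species analysis (IndVal)
#'
#' For each ASV and group, the indicator value is
#' \eqn{\sqrt{A \cdot B}} where \eqn{A} (specificity) is the group's mean
#' abundance divided by the sum of all groups' mean abundances and \eqn{B}
#' (fidelity) is the fraction of the group's samples where the ASV is
#' present. The reported statistic is the maximum over groups; its p-value
#' comes from permuting group labels (add-one Monte-Carlo estimator, or the
#' exact proportion over all distinct label assignments with
#' `n_perm = "exact"`, feasible for n of 10 or fewer samples). Specificity
#' uses per-group mean abundance by default, which corrects for unequal
#' group sizes; `specificity = "total"` uses raw per-group abundance sums
#' instead.
#'
#' @param table [asv_table].
#' @param groups Character/factor vector of group labels, one per table
#'   sample (at least 2 non-empty groups).
#' @param n_perm Number of label permutations, or `"exact"`.
#' @param seed RNG seed for Monte-Carlo permutations.
#' @param specificity `"mean"` (group-size-corrected) or `"total"`.
#' @return Tibble with `asv_id`, `stat`, `best_group`, `p_value` (`NA`
#'   statistic for ASVs absent everywhere).
#' @export
indval <- function(table, groups, n_perm = 999, seed = 1,
                   specificity = c("mean", "total")) {
  specificity <- match.arg(specificity)
  m <- unclass(table)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  if (length(unique(groups)) < 2)
    abort("indval() needs at least two groups.")
  obs <- indval_stats(m, groups, specificity)
  exact <- identical(n_perm, "exact")
  if (exact) {
    perms <- enumerate_group_permutations(groups)
    ge <- rep(0L, ncol(m))
    for (k in seq_len(ncol(perms))) {
      st <- indval_stats(m, groups[perms[, k]], specificity)$stat
      ge <- ge + as.integer(!is.na(st) & !is.na(obs$stat) &
                              st >= obs$stat - 1e-12)
    }
    p <- ge / ncol(perms)
  } else {
    ge <- rep(0L, ncol(m))
    with_seed(seed, {
      for (k in seq_len(n_perm)) {
        st <- indval_stats(m, sample(groups), specificity)$stat
        ge <- ge + as.integer(!is.na(st) & !is.na(obs$stat) &
                                st >= obs$stat - 1e-12)
      }
    })
    p <- (1 + ge) / (1 + n_perm)
  }
  p[is.na(obs$stat)] <- NA_real_
  tibble::tibble(asv_id = colnames(m), stat = unname(obs$stat),
                 best_group = unname(obs$best), p_value = unname(p))
}

#' Indicator core: ASVs enriched in the plant over bulk soil
#'
#' Runs [indval()] with a plant-versus-soil grouping derived from the
#' metadata and keeps ASVs whose best group is the plant and whose
#' permutation p-value is at most `alpha`. Benjamini-Hochberg correction
#' across ASVs is available via `adjust`.
#'
#' @param table [asv_table] containing both plant and soil samples.
#' @param metadata Sample metadata (`tissue == "soil"` marks soil).
#' @param alpha Significance threshold on the (optionally adjusted)
#'   p-value.
#' @param n_perm,seed Passed to [indval()].
#' @param adjust Apply Benjamini-Hochberg correction before thresholding.
#' @return Character vector of core ASV identifiers; the full per-ASV
#'   table is attached as attribute `indval`.
#' @export
indicator_core <- function(table, metadata, alpha = 0.05, n_perm = 999,
                           seed = 1, adjust = FALSE) {
  al <- align_samples(table, metadata)
  groups <- ifelse(al$metadata$tissue == "soil", "soil", "plant")
  if (!any(groups == "soil"))
    abort("indicator_core() needs soil samples for contrast.")
  if (!any(groups == "plant"))
    abort("indicator_core() needs plant samples.")
  res <- indval(al$table, groups, n_perm = n_perm, seed = seed)
  p <- if (adjust) p.adjust(res$p_value, method = "BH") else res$p_value
  keep <- !is.na(res$stat) & res$best_group == "plant" & !is.na(p) &
    p <= alpha
  out <- res$asv_id[keep]
  attr(out, "indval") <- res
  out
}

#' Apply a core-membership rule to a table
#'
#' Convenience filter keeping only the columns named by a core rule.
#'
#' @param table [asv_table].
#' @param core_ids ASV identifiers from [core_a()], [core_b()] or
#'   [indicator_core()].
#' @return The filtered [asv_table].
#' @export
filter_core <- function(table, core_ids) {
  table[, colnames(table) %in% core_ids, drop = FALSE]
}
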