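#' Tissue subset schemes for within-individual analyses
#'
#' Within-plant comparisons only make sense for plants where every tissue
#' of interest was recovered. Three schemes are supported:
#' `"all_tissues"` demands every tissue present at the plant's
#' developmental stage (a ripe-silique plant needs all seven tissues),
#' `"root_rosette"` demands roots and rosettes only (so every stage
#' qualifies), and `"aerial_no_siliques"` demands rosette, stem, cauline
#' leaf and flower — the aerial organs whose selective environment differs
#' sharply from the root's, silique tissues excluded.
#'
#' @param scheme Scheme name.
#' @param stage Developmental stage (used by `"all_tissues"`).
#' @return Character vector of required tissues.
#' @export
scheme_tissues <- function(scheme = c("all_tissues", "root_rosette",
                                      "aerial_no_siliques"),
                           stage = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    all_tissues = {
      if (is.null(stage)) abort("all_tissues scheme needs the stage.")
      stage_tissues()[[stage]]
    },
    root_rosette = c("root", "rosette"),
    aerial_no_siliques = c("rosette", "stem", "cauline_leaf", "flower"))
}

#' Plants with a complete tissue set under a scheme
#'
#' @param metadata Sample metadata (plant samples).
#' @param scheme One of the [scheme_tissues()] schemes.
#' @return Tibble of qualifying plants: `plant_id`, `genotype`, `stage`,
#'   `n_tissues`.
#' @export
select_complete_plants <- function(metadata,
                                   scheme = c("all_tissues", "root_rosette",
                                              "aerial_no_siliques")) {
  scheme <- match.arg(scheme)
  md <- metadata[metadata$tissue != "soil", , drop = FALSE]
  plants <- dplyr::distinct(md, .data$plant_id, .data$genotype, .data$stage)
  ok <- vapply(seq_len(nrow(plants)), function(i) {
    req <- scheme_tissues(scheme, stage = plants$stage[i])
    have <- md$tissue[md$plant_id == plants$plant_id[i]]
    all(req %in% have)
  }, logical(1))
  out <- plants[ok, , drop = FALSE]
  out$n_tissues <- vapply(out$stage, function(s)
    length(scheme_tissues(scheme, stage = s)), numeric(1))
  tibble::as_tibble(out)
}

#' Within-plant tissue homogeneity
#'
#' Quantifies how alike the tissue communities of one plant are: the
#' plant's tissue samples are embedded by [pcoa_embed()], the spatial
#' median of the embedded points (the plant's "median community") is
#' located, and the mean of the tissues' corrected distances to that
#' median is returned. Zero means identical tissue communities; larger
#' values mean stronger tissue specificity.
#'
#' @param dm [dist_matrix] over one plant's tissue samples (at least 2).
#' @return Mean distance to the median community (single number).
#' @export
plant_homogeneity <- function(dm) {
  dm <- dist_matrix(dm)
  if (nrow(dm) < 2)
    abort("plant_homogeneity() needs at least two tissues.")
  emb <- pcoa_embed(dm)
  cr <- spatial_median(emb$real)
  ci <- spatial_median(emb$imaginary)
  mean(corrected_center_distance(emb$real, emb$imaginary, cr, ci))
}

#' Within-individual tissue-specificity analysis
#'
#' For every plant with a complete tissue set under the scheme, computes
#' Bray-Curtis dissimilarities among that plant's tissue communities and
#' the plant's mean distance-to-median ([plant_homogeneity()]); then tests
#' whether developmental stage and genotype shift this homogeneity
#' statistic with a stage-by-genotype univariate permutational ANOVA and
#' pairwise stage post-hocs under Benjamini-Hochberg correction.
#'
#' @param table [asv_table] (typically quality-filtered counts or a
#'   repeat-rarefied mean table).
#' @param metadata Sample metadata.
#' @param scheme Tissue scheme, see [scheme_tissues()].
#' @param n_perm,seed Permutation settings.
#' @param global_embedding Embed all selected samples in one ordination
#'   and locate each plant's median there, instead of the default
#'   per-plant embedding (sensitivity analysis).
#' @return A `homogeneity_result` list: `plants` (per-plant tibble with
#'   `mean_dist_to_median`), `test` (`perm_test`), and `pairwise_stage`
#'   (tibble, `NULL` when only one stage qualifies).
#' @export
homogeneity_analysis <- function(table, metadata,
                                 scheme = c("all_tissues", "root_rosette",
                                            "aerial_no_siliques"),
                                 n_perm = 999, seed = 1,
                                 global_embedding = FALSE) {
  scheme <- match.arg(scheme)
  al <- align_samples(table, metadata)
  sel <- select_complete_plants(al$metadata, scheme)
  if (nrow(sel) == 0) abort("No plant has the scheme's full tissue set.")
  cells <- table(paste(sel$stage, sel$genotype))
  if (any(cells < 2))
    abort(paste0("Design cell ", names(cells)[cells < 2][1],
                 " has a single plant: cannot test."))
  md <- al$metadata
  vals <- numeric(nrow(sel))
  if (global_embedding) {
    wanted <- md$plant_id %in% sel$plant_id & vapply(
      seq_len(nrow(md)), function(i)
        md$tissue[i] %in% scheme_tissues(scheme, stage = md$stage[i]),
      logical(1))
    ids <- md$sample_id[wanted]
    dmg <- distance_matrix(al$table[ids, , drop = FALSE], "bray_curtis")
    emb <- pcoa_embed(dmg)
    for (i in seq_len(nrow(sel))) {
      pid <- sel$plant_id[i]
      idx <- md$plant_id[match(rownames(dmg), md$sample_id)] == pid
      R <- emb$real[idx, , drop = FALSE]
      I <- emb$imaginary[idx, , drop = FALSE]
      vals[i] <- mean(corrected_center_distance(
        R, I, spatial_median(R), spatial_median(I)))
    }
  } else {
    for (i in seq_len(nrow(sel))) {
      pid <- sel$plant_id[i]
      req <- scheme_tissues(scheme, stage = sel$stage[i])
      ids <- md$sample_id[md$plant_id == pid & md$tissue %in% req]
      dmp <- distance_matrix(al$table[ids, , drop = FALSE], "bray_curtis")
      vals[i] <- plant_homogeneity(dmp)
    }
  }
  plants <- dplyr::mutate(sel, mean_dist_to_median = vals)

  md_test <- tibble::tibble(sample_id = plants$plant_id,
                            stage = plants$stage,
                            genotype = plants$genotype)
  vary <- c(stage = length(unique(plants$stage)) > 1,
            genotype = length(unique(plants$genotype)) > 1)
  rhs <- if (all(vary)) "stage * genotype" else
    if (vary[["stage"]]) "stage" else if (vary[["genotype"]]) "genotype" else
      abort("Neither stage nor genotype varies among selected plants.")
  fit <- perm_anova_univariate(
    setNames(plants$mean_dist_to_median, plants$plant_id),
    md_test, as.formula(paste("~", rhs)), n_perm = n_perm, seed = seed)

  pairwise <- NULL
  if (vary[["stage"]]) {
    D <- abs(outer(plants$mean_dist_to_median,
                   plants$mean_dist_to_median, "-"))
    rownames(D) <- colnames(D) <- plants$plant_id
    pairwise <- permanova_pairwise(dist_matrix(D), md_test, "stage",
                                   n_perm = n_perm, seed = seed)
  }
  structure(list(plants = plants, test = fit, pairwise_stage = pairwise,
                 scheme = scheme),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("<homogeneity_result> scheme '%s', %d plants\n",
              x$scheme, nrow(x$plants)))
  print(x$test)
  invisible(x)
}
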