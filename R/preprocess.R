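#' Separate spike-in reads from experimental reads
#'
#' Splits an ASV table into its experimental columns and a per-sample
#' tabulation of spike-in reads. Per-sample totals are conserved exactly:
#' experimental + spike reads equal the original total for every sample.
#'
#' @param table An [asv_table] containing (possibly zero) spike columns.
#' @param registry A [spike_registry]; its IDs must be a subset of the
#'   table's ASV IDs (an empty registry yields zero spike reads).
#' @return List with `experimental` (the [asv_table] without spike columns)
#'   and `spikes`, a tibble with `sample_id`, `spike_reads`, `total_reads`
#'   and `spike_fraction`.
#' @export
split_spikes <- function(table, registry) {
  ids <- registry$spike_ids
  missing_ids <- setdiff(ids, colnames(table))
  if (length(missing_ids) > 0)
    abort(paste0("Spike IDs absent from table: ",
                 paste(missing_ids, collapse = ", ")))
  is_spike <- colnames(table) %in% ids
  spike_reads <- if (any(is_spike))
    rowSums(table[, is_spike, drop = FALSE]) else
    setNames(numeric(nrow(table)), rownames(table))
  experimental <- table[, !is_spike, drop = FALSE]
  total <- spike_reads + rowSums(experimental)
  list(
    experimental = experimental,
    spikes = tibble::tibble(
      sample_id = rownames(table),
      spike_reads = as.numeric(spike_reads),
      total_reads = as.numeric(total),
      spike_fraction = ifelse(total > 0, spike_reads / total, NA_real_))
  )
}

#' Admit samples to absolute quantitation by spike fraction
#'
#' Only samples whose spike reads make up between `lo` and `hi` of the total
#' read count (bounds inclusive, defaults 20%--80%) are quantifiable: below
#' the window the spike signal is too noisy, above it the sample is mostly
#' spike. Zero-total samples are excluded with their own reason.
#'
#' @param spikes The `spikes` tibble from [split_spikes()].
#' @param lo,hi Inclusive admission bounds on the spike fraction.
#' @return The input tibble with logical `admitted` and character `reason`
#'   (`NA` for admitted samples) columns added.
#' @export
spike_admission_filter <- function(spikes, lo = 0.2, hi = 0.8) {
  stopifnot(lo <= hi)
  f <- spikes$spike_fraction
  reason <- dplyr::case_when(
    spikes$total_reads <= 0 ~ "zero_total",
    f < lo ~ "spike_fraction_below",
    f > hi ~ "spike_fraction_above",
    TRUE ~ NA_character_)
  dplyr::mutate(spikes, admitted = is.na(reason), reason = reason)
}

#' Dataset-wide reference spike count
#'
#' The median spike read count over the admitted samples, used as the
#' numerator of the absolute scaling factor.
#'
#' @param spikes Output of [spike_admission_filter()] (or the raw
#'   [split_spikes()] tibble with `admitted_only = FALSE`).
#' @param admitted_only Restrict the median to admitted samples (default).
#' @return A single number.
#' @export
spike_median <- function(spikes, admitted_only = TRUE) {
  x <- if (admitted_only && "admitted" %in% names(spikes))
    spikes$spike_reads[spikes$admitted] else spikes$spike_reads
  if (length(x) == 0) abort("No samples available for the spike median.")
  median(x)
}

#' Scale experimental counts to an absolute scale via spike-ins
#'
#' Each sample's experimental counts are multiplied by
#' `spike_median / spike_sample`, so that a sample that recovered few spike
#' reads (i.e. carried much microbial template) is scaled up and vice
#' versa. Within-sample relative abundances are unchanged.
#'
#' @param experimental Experimental [asv_table] (spike columns removed).
#' @param spike_counts Named numeric vector (or `spikes` tibble) of spike
#'   reads per sample; must be positive for every sample scaled.
#' @param reference The dataset-wide median spike count ([spike_median()]).
#' @return An [asv_table] on the absolute scale.
#' @export
scale_by_spike <- function(experimental, spike_counts, reference) {
  if (is.data.frame(spike_counts))
    spike_counts <- setNames(spike_counts$spike_reads,
                             spike_counts$sample_id)
  sc <- spike_counts[rownames(experimental)]
  if (anyNA(sc))
    abort("Missing spike counts for some samples in the table.")
  if (any(sc <= 0))
    abort(paste0("Zero spike reads in admitted sample '",
                 rownames(experimental)[which(sc <= 0)[1]],
                 "': cannot quantify."))
  if (!is.numeric(reference) || reference <= 0)
    abort("Reference spike median must be positive.")
  scaled <- unclass(experimental) * (reference / as.numeric(sc))
  asv_table(scaled, amplicon = attr(experimental, "amplicon"))
}

#' Read-count quality filtering
#'
#' Drops low-information items from a raw count table in a fixed order:
#' first samples whose total read count is below `min_sample_reads`
#' (default 500), then ASVs whose dataset-wide total (over the surviving
#' samples) is below `min_asv_reads` (default 10). Optionally excludes
#' samples of flagged tissues (e.g. senescent siliques) beforehand. The
#' filter is idempotent.
#'
#' @param table Raw (pre-scaling) [asv_table].
#' @param min_sample_reads,min_asv_reads Inclusive keep-thresholds: a
#'   sample/ASV is dropped when its total is strictly below the threshold.
#' @param exclude_tissues Optional character vector of tissues to drop
#'   up-front; requires `metadata`.
#' @param metadata Sample metadata (only needed with `exclude_tissues`).
#' @return List with `table` (the filtered [asv_table]) and `report`, a
#'   `qc_report` listing every dropped sample/ASV with one primary reason.
#' @export
quality_filter <- function(table, min_sample_reads = 500, min_asv_reads = 10,
                           exclude_tissues = NULL, metadata = NULL) {
  dropped_samples <- tibble::tibble(sample_id = character(),
                                    reason = character())
  tab <- table
  if (!is.null(exclude_tissues)) {
    if (is.null(metadata))
      abort("Tissue exclusion requires metadata.")
    bad <- metadata$sample_id[metadata$tissue %in% exclude_tissues]
    bad <- intersect(rownames(tab), bad)
    if (length(bad) > 0) {
      dropped_samples <- dplyr::bind_rows(
        dropped_samples,
        tibble::tibble(sample_id = bad, reason = "excluded_tissue"))
      tab <- tab[setdiff(rownames(tab), bad), , drop = FALSE]
    }
  }
  low <- rowSums(tab) < min_sample_reads
  if (any(low)) {
    dropped_samples <- dplyr::bind_rows(
      dropped_samples,
      tibble::tibble(sample_id = rownames(tab)[low],
                     reason = "low_sample_reads"))
    tab <- tab[!low, , drop = FALSE]
  }
  low_asv <- colSums(tab) < min_asv_reads
  dropped_asvs <- tibble::tibble(asv_id = colnames(tab)[low_asv],
                                 reason = "low_asv_reads")
  tab <- tab[, !low_asv, drop = FALSE]
  warn_empty <- nrow(tab) == 0 || ncol(tab) == 0
  if (warn_empty)
    warn("Quality filtering removed every sample or ASV.")
  report <- structure(
    list(dropped_samples = dropped_samples, dropped_asvs = dropped_asvs,
         n_samples_kept = nrow(tab), n_asvs_kept = ncol(tab),
         empty = warn_empty,
         thresholds = c(min_sample_reads = min_sample_reads,
                        min_asv_reads = min_asv_reads)),
    class = "qc_report")
  list(table = tab, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> kept %d samples / %d ASVs; dropped %d samples, %d ASVs\n",
    x$n_samples_kept, x$n_asvs_kept,
    nrow(x$dropped_samples), nrow(x$dropped_asvs)))
  invisible(x)
}

#' Per-sample microbial load
#'
#' On a spike-scaled table the row sum estimates the total microbial load
#' of the sample, comparable across samples.
#'
#' @param scaled A spike-scaled [asv_table] (see [scale_by_spike()]).
#' @return Tibble with `sample_id` and `load`.
#' @export
microbial_load <- function(scaled) {
  tibble::tibble(sample_id = rownames(scaled),
                 load = as.numeric(rowSums(scaled)))
}
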