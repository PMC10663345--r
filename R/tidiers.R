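#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutational test
#'
#' Broom-style accessors for `perm_test` objects: `tidy()` returns the
#' per-term variance partition (SS, df, R-squared, pseudo-F, permutation
#' p), optionally with residual and total rows appended; `glance()`
#' returns a one-row model summary.
#'
#' @param x A `perm_test` (from [permanova()], [permdisp()],
#'   [perm_anova_univariate()] or [homogeneity_analysis()]`$test`).
#' @param include_residual Append residual and total rows.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, include_residual = FALSE, ...) {
  out <- x$terms
  if (include_residual) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(term = "Residual", df = x$df_residual,
                     ss = x$residual_ss,
                     r_squared = x$residual_ss / x$total_ss,
                     pseudo_f = NA_real_, p_value = NA_real_),
      tibble::tibble(term = "Total",
                     df = sum(x$terms$df) + x$df_residual,
                     ss = x$total_ss, r_squared = 1,
                     pseudo_f = NA_real_, p_value = NA_real_))
  }
  out
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(total_ss = x$total_ss, residual_ss = x$residual_ss,
                 df_residual = x$df_residual, n_perm = x$n_perm,
                 method = x$method, permutation = x$permutation)
}

#' @rdname tidy.perm_test
#' @method tidy homogeneity_result
#' @export
tidy.homogeneity_result <- function(x, ...) tidy(x$test, ...)

#' @rdname tidy.perm_test
#' @method glance homogeneity_result
#' @export
glance.homogeneity_result <- function(x, ...) glance(x$test, ...)

#' Tidy a PCoA embedding
#'
#' Returns per-sample coordinates on the leading real axes together with
#' the fraction of positive eigenvalue mass each axis carries.
#'
#' @param x A `pcoa_embedding`.
#' @param n_axes Number of real axes to return.
#' @param ... Unused.
#' @return Tibble with `sample_id` and `PCo1..PCok` columns; axis variance
#'   fractions are in the `axis_variance` attribute.
#' @method tidy pcoa_embedding
#' @export
tidy.pcoa_embedding <- function(x, n_axes = 2, ...) {
  k <- min(n_axes, ncol(x$real))
  coords <- x$real[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  out <- tibble::as_tibble(coords)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), out)
  pos <- x$eigenvalues[x$eigenvalues > 0]
  attr(out, "axis_variance") <- pos[seq_len(k)] / sum(pos)
  out
}
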