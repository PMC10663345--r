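#' Gower-centred inner-product matrix of a distance matrix
#'
#' Computes \eqn{G = -\tfrac12 J D^{(2)} J} where \eqn{D^{(2)}} holds the
#' squared dissimilarities and \eqn{J = I - \mathbf{1}\mathbf{1}'/n} is the
#' centring projector. `trace(G)` is the total sum of squares of the
#' configuration (Huygens: \eqn{\sum_{i<j} d_{ij}^2 / n}); all
#' distance-based partitioning below works on this matrix.
#'
#' @param dm A [dist_matrix] (or coercible square matrix / `dist`).
#' @return Symmetric numeric matrix with (numerically) zero row sums.
#' @export
gower_center <- function(dm) {
  d2 <- unclass(dist_matrix(dm))^2
  n <- nrow(d2)
  a <- -0.5 * d2
  rm_ <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  (g + t(g)) / 2
}

# Orthonormal bases per model term (sequential, intercept first), returning
# per-term projector increments and degrees of freedom.
build_term_projectors <- function(formula, metadata) {
  tt <- terms(formula, keep.order = TRUE)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0) abort("Model has no terms.")
  mm <- model.matrix(tt, data = as.data.frame(metadata))
  asgn <- attr(mm, "assign")
  n <- nrow(mm)
  basis <- matrix(1 / sqrt(n), n, 1)
  proj <- list(); dfs <- integer(length(labels))
  for (k in seq_along(labels)) {
    Xk <- mm[, asgn == k, drop = FALSE]
    R <- Xk - basis %*% crossprod(basis, Xk)
    qrk <- qr(R)
    tol <- max(dim(R)) * .Machine$double.eps * max(abs(qr.R(qrk)), 1)
    rk <- sum(abs(diag(qr.R(qrk))) > tol)
    if (rk > 0) {
      Qk <- qr.Q(qrk)[, seq_len(rk), drop = FALSE]
      proj[[k]] <- tcrossprod(Qk)
      basis <- cbind(basis, Qk)
    } else {
      proj[[k]] <- matrix(0, n, n)
    }
    dfs[k] <- rk
  }
  list(labels = labels, proj = proj, df = dfs,
       rank_model = ncol(basis) - 1L, n = n)
}

# permutation index matrix: n x n_perm, optionally restricted to shuffle
# within strata; exact = all n! permutations (identity included)
make_permutations <- function(n, n_perm, seed, strata = NULL,
                              exact = FALSE) {
  if (exact) {
    if (!is.null(strata))
      abort("Exact enumeration is not implemented with strata.")
    if (n > 8) abort("Exact enumeration limited to n <= 8.")
    all_perm <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in all_perm(v[-i]))
          out[[length(out) + 1]] <- c(v[i], rest)
      out
    }
    return(do.call(cbind, all_perm(seq_len(n))))
  }
  with_seed(seed, {
    if (is.null(strata)) {
      matrix(replicate(n_perm, sample.int(n)), nrow = n)
    } else {
      strata <- as.character(strata)
      matrix(replicate(n_perm, {
        p <- seq_len(n)
        for (lev in unique(strata)) {
          idx <- which(strata == lev)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }), nrow = n)
    }
  })
}

new_perm_test <- function(terms_tbl, residual_ss, total_ss, df_residual,
                          n_perm, method, permutation = "free") {
  structure(list(terms = terms_tbl, residual_ss = residual_ss,
                 total_ss = total_ss, df_residual = df_residual,
                 n_perm = n_perm, method = method,
                 permutation = permutation),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s | %s permutations\n", x$method,
              format(x$n_perm)))
  print(as.data.frame(x$terms), digits = 4)
  cat(sprintf("Residual SS %.4g (df %d); total SS %.4g\n",
              x$residual_ss, x$df_residual, x$total_ss))
  invisible(x)
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a dissimilarity matrix among the
#' model terms by projecting the Gower-centred matrix onto the terms'
#' design subspaces. Sums of squares are sequential (Type I) in the order
#' the formula states (use `keep.order` semantics: write the blocking term
#' first, e.g. `~ run:plate + tissue * stage * genotype`); marginal SS is
#' available via `ss = "margin"`. The pseudo-F for each term is
#' `(SS_term / df_term) / (SS_res / df_res)`; p-values come from permuting
#' sample identities of the distance matrix and recomputing every
#' statistic, with the add-one estimator `(1 + #\{F* >= F\}) / (1 + B)`.
#' Ties count toward the numerator. `n_perm = "exact"` enumerates all
#' permutations (n of 8 or fewer) and reports the exact proportion.
#' `strata` restricts permutations to exchange samples only within the
#' given blocks.
#'
#' @param dm A [dist_matrix] (rows named by sample).
#' @param metadata Data frame with `sample_id` and the model variables.
#' @param formula Right-hand-side model formula over metadata columns.
#' @param n_perm Number of permutations (default 999) or `"exact"`.
#' @param seed RNG seed for the permutation stream.
#' @param strata Optional metadata column name: permutations shuffle
#'   within its levels only.
#' @param ss `"sequential"` (Type I, default) or `"margin"`.
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @export
permanova <- function(dm, metadata, formula, n_perm = 999, seed = 1,
                      strata = NULL, ss = c("sequential", "margin")) {
  ss <- match.arg(ss)
  dm <- dist_matrix(dm)
  md <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    abort("Every sample in the distance matrix needs metadata.")
  G <- gower_center(dm)
  n <- nrow(G)
  bp <- build_term_projectors(formula, md)
  df_res <- n - 1L - bp$rank_model
  if (df_res <= 0) abort("Model saturates the data: no residual df.")
  total_ss <- sum(diag(G))

  strata_vec <- if (!is.null(strata)) md[[strata]] else NULL
  exact <- identical(n_perm, "exact")
  if (exact) {
    perms <- make_permutations(n, NULL, seed, strata_vec, exact = TRUE)
    n_perm_eff <- ncol(perms)
  } else {
    perms <- make_permutations(n, n_perm, seed, strata_vec)
    n_perm_eff <- n_perm
  }

  stat_fun <- function(Gp) {
    ssk <- vapply(bp$proj, function(P) sum(P * Gp), numeric(1))
    res <- max(sum(diag(Gp)) - sum(ssk), 0)
    # res = 0 with positive term SS gives F = Inf (perfect fit); a fully
    # degenerate matrix gives NaN, reported as NA downstream
    f <- (ssk / pmax(bp$df, 1)) / (res / df_res)
    f[bp$df == 0] <- NA_real_
    list(ss = ssk, res = res, f = f)
  }

  if (ss == "margin") {
    # projector of each term fitted after all others (position-last
    # sequential increment); residual comes from the full model
    marg_proj <- lapply(seq_along(bp$labels), function(k) {
      reordered <- stats::reformulate(c(bp$labels[-k], bp$labels[k]))
      bpk <- build_term_projectors(reordered, md)
      bpk$proj[[length(bpk$proj)]]
    })
    stat_fun <- function(Gp) {
      ss_seq <- vapply(bp$proj, function(P) sum(P * Gp), numeric(1))
      res <- max(sum(diag(Gp)) - sum(ss_seq), 0)
      ssk <- vapply(marg_proj, function(P) sum(P * Gp), numeric(1))
      f <- (ssk / pmax(bp$df, 1)) / (res / df_res)
      f[bp$df == 0] <- NA_real_
      list(ss = ssk, res = res, f = f)
    }
  }

  obs <- stat_fun(G)
  ge <- numeric(length(bp$labels))
  eps <- ifelse(is.finite(obs$f), 1e-8 * (1 + abs(obs$f)), 0)
  for (b in seq_len(n_perm_eff)) {
    p <- perms[, b]
    Gp <- G[p, p]
    st <- stat_fun(Gp)
    ge <- ge + as.numeric(!is.na(st$f) & !is.na(obs$f) &
                            st$f >= obs$f - eps)
  }
  pvals <- if (exact) ge / n_perm_eff else (1 + ge) / (1 + n_perm_eff)
  pvals[is.na(obs$f)] <- NA_real_

  terms_tbl <- tibble::tibble(
    term = bp$labels, df = bp$df, ss = obs$ss,
    r_squared = obs$ss / total_ss,
    pseudo_f = obs$f, p_value = pvals)
  new_perm_test(terms_tbl, obs$res, total_ss, df_res,
                n_perm_eff, paste0("PERMANOVA (", ss, " SS)"),
                permutation = if (!is.null(strata))
                  paste0("within ", strata) else "free")
}

#' Pairwise post-hoc PERMANOVA with Benjamini-Hochberg correction
#'
#' Tests every pair of levels of a factor by a one-factor [permanova()] on
#' just that pair's samples, optionally restricted to a subset of the
#' design (e.g. one developmental stage), and adjusts the p-values across
#' the pair family by the Benjamini-Hochberg step-up rule. Pairs where a
#' level has fewer than two samples are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param dm [dist_matrix].
#' @param metadata Sample metadata.
#' @param factor_name Metadata column whose levels are compared.
#' @param levels Optional subset of levels (default: all present).
#' @param within Optional named list of `column = value` filters applied
#'   before testing.
#' @param n_perm,seed Passed to [permanova()].
#' @return Tibble with one row per tested pair: `level_1`, `level_2`, `n`,
#'   `ss`, `r_squared`, `pseudo_f`, `p_value`, `p_adjusted`.
#' @export
permanova_pairwise <- function(dm, metadata, factor_name, levels = NULL,
                               within = NULL, n_perm = 999, seed = 1) {
  dm <- dist_matrix(dm)
  md <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(md))
  for (col in names(within)) keep <- keep & md[[col]] %in% within[[col]]
  md <- md[keep, , drop = FALSE]
  lv <- levels %||% sort(unique(md[[factor_name]]))
  if (length(lv) < 2) abort("Need at least two levels to compare.")
  pairs <- combn(lv, 2)
  rows <- list(); skipped <- character()
  for (j in seq_len(ncol(pairs))) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    sel <- md$sample_id[md[[factor_name]] %in% c(l1, l2)]
    sub_md <- md[md$sample_id %in% sel, , drop = FALSE]
    if (sum(sub_md[[factor_name]] == l1) < 2 ||
        sum(sub_md[[factor_name]] == l2) < 2) {
      skipped <- c(skipped, paste(l1, l2, sep = " vs "))
      next
    }
    sub_dm <- dist_matrix(unclass(dm)[sel, sel])
    fit <- permanova(sub_dm, sub_md,
                     as.formula(paste0("~ `", factor_name, "`")),
                     n_perm = n_perm, seed = seed)
    tt <- fit$terms[1, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      level_1 = l1, level_2 = l2, n = nrow(sub_md), ss = tt$ss,
      r_squared = tt$r_squared, pseudo_f = tt$pseudo_f,
      p_value = tt$p_value)
  }
  if (length(rows) == 0) abort("No testable pairs.")
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Principal coordinates analysis with imaginary axes
#'
#' Eigendecomposition of the Gower-centred matrix. Axes with positive
#' eigenvalues are scaled by \eqn{\sqrt{\lambda}} and form the real block;
#' axes with negative eigenvalues (which arise for semi-metric
#' dissimilarities like Bray-Curtis) are kept as an imaginary block scaled
#' by \eqn{\sqrt{|\lambda|}}. Squared inter-point distances are recovered
#' as real-block squared differences minus imaginary-block squared
#' differences.
#'
#' @param dm A [dist_matrix].
#' @return A `pcoa_embedding` list: `real` (n x a), `imaginary` (n x b),
#'   `eigenvalues`, `sample_ids`.
#' @export
pcoa_embed <- function(dm) {
  dm <- dist_matrix(dm)
  G <- gower_center(dm)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values), 1e-300) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  real <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), nrow = sum(pos))
  imaginary <- eg$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eg$values[neg]), nrow = sum(neg))
  rownames(real) <- rownames(imaginary) <- rownames(dm)
  structure(list(real = real, imaginary = imaginary,
                 eigenvalues = eg$values, sample_ids = rownames(dm)),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat(sprintf("<pcoa_embedding> %d samples; %d real / %d imaginary axes\n",
              length(x$sample_ids), ncol(x$real), ncol(x$imaginary)))
  invisible(x)
}

# L1 (spatial) median of the rows of X by damped Weiszfeld iteration
spatial_median <- function(X, tol = 1e-8, maxit = 5000) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(numeric(0))
  y <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2, y)^2))
    d <- pmax(d, 1e-12)                    # damping at coincident points
    w <- 1 / d
    y_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) <= tol * (1 + sqrt(sum(y^2)))) {
      return(y_new)
    }
    y <- y_new
  }
  y
}

# corrected distance of embedded points to a (real, imaginary) center
corrected_center_distance <- function(real, imaginary, c_real, c_imag) {
  d2r <- if (ncol(real) > 0)
    rowSums(sweep(real, 2, c_real)^2) else numeric(nrow(real))
  d2i <- if (ncol(imaginary) > 0)
    rowSums(sweep(imaginary, 2, c_imag)^2) else numeric(nrow(imaginary))
  sqrt(pmax(d2r - d2i, 0))
}

oneway_f <- function(d, groups) {
  gl <- split(d, groups)
  n <- length(d); g <- length(gl)
  gm <- mean(d)
  ssb <- sum(vapply(gl, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw <= 1e-300 && ssb <= 1e-300) return(NA_real_)
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Embeds the distance matrix by [pcoa_embed()], computes each group's
#' centre (spatial median by default, computed separately on the real and
#' imaginary blocks; centroid optional), and each sample's corrected
#' distance to its own group centre (real-block squared distance minus
#' imaginary-block squared distance, floored at zero). Equality of group
#' dispersions is tested by the one-way ANOVA F on these distances with a
#' permutation p-value obtained by shuffling group labels.
#'
#' @param dm [dist_matrix].
#' @param groups Group label per sample (named vector, or aligned to the
#'   matrix row order).
#' @param center `"spatial_median"` (default) or `"centroid"`.
#' @param n_perm,seed Permutation settings.
#' @return A `permdisp` object: a `perm_test` plus `distances`, a tibble
#'   of per-sample distances to group centres.
#' @export
permdisp <- function(dm, groups, center = c("spatial_median", "centroid"),
                     n_perm = 999, seed = 1) {
  center <- match.arg(center)
  dm <- dist_matrix(dm)
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  tabg <- table(groups)
  if (any(tabg < 2))
    abort(paste0("Group '", names(tabg)[tabg < 2][1],
                 "' has fewer than 2 samples."))
  emb <- pcoa_embed(dm)
  d <- numeric(nrow(dm))
  for (g in unique(groups)) {
    idx <- groups == g
    R <- emb$real[idx, , drop = FALSE]
    I <- emb$imaginary[idx, , drop = FALSE]
    if (center == "centroid") {
      cr <- colMeans(R); ci <- colMeans(I)
    } else {
      cr <- spatial_median(R); ci <- spatial_median(I)
    }
    d[idx] <- corrected_center_distance(R, I, cr, ci)
  }
  f_obs <- oneway_f(d, groups)
  g <- length(unique(groups)); n <- length(d)
  if (is.na(f_obs)) {
    p <- NA_real_
    ge <- NA_real_
  } else {
    perms <- make_permutations(n, n_perm, seed)
    eps <- 1e-8 * (1 + abs(f_obs))
    ge <- 0
    for (b in seq_len(n_perm)) {
      fp <- oneway_f(d, groups[perms[, b]])
      if (!is.na(fp) && fp >= f_obs - eps) ge <- ge + 1
    }
    p <- (1 + ge) / (1 + n_perm)
  }
  gm <- mean(d)
  ssb <- sum(vapply(split(d, groups), function(v)
    length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(split(d, groups), function(v)
    sum((v - mean(v))^2, na.rm = TRUE), numeric(1)))
  terms_tbl <- tibble::tibble(
    term = "group", df = g - 1L, ss = ssb,
    r_squared = if (ssb + ssw > 0) ssb / (ssb + ssw) else NA_real_,
    pseudo_f = f_obs, p_value = p)
  out <- new_perm_test(terms_tbl, ssw, ssb + ssw, n - g, n_perm,
                       paste0("PERMDISP (", center, ")"))
  out$distances <- tibble::tibble(sample_id = rownames(dm),
                                  group = groups, distance = d)
  class(out) <- c("permdisp", class(out))
  out
}

#' Univariate permutational ANOVA
#'
#' Permutational ANOVA of a single numeric response: implemented as
#' [permanova()] on the Euclidean distance matrix of the response, whose
#' sums of squares and F statistics coincide exactly with classical ANOVA,
#' while p-values come from permutation.
#'
#' @param response Numeric vector, named by sample/plant identifier (or
#'   aligned with `metadata` rows).
#' @param metadata Data frame with `sample_id` and the model variables.
#' @param formula Model formula (e.g. `~ tissue * stage * genotype`).
#' @param ... Passed to [permanova()] (`n_perm`, `seed`, `strata`, `ss`).
#' @return A `perm_test` object. Constant responses have zero total SS and
#'   yield `NA` statistics.
#' @export
perm_anova_univariate <- function(response, metadata, formula, ...) {
  ids <- names(response) %||% metadata$sample_id
  if (length(ids) != length(response))
    abort("Response and metadata lengths differ.")
  D <- abs(outer(response, response, "-"))
  rownames(D) <- colnames(D) <- ids
  permanova(dist_matrix(D), metadata, formula, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
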