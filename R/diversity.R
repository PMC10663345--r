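#' Rarefaction scheme
#'
#' Repeated rarefaction draws each sample down to a common depth many times
#' and averages, which controls for sequencing-depth variation without the
#' information loss of a single random draw. Default depths follow the
#' marker gene: 1380 reads for 16S, 751 for ITS1.
#'
#' @param depth Target depth (reads per sample), or an amplicon name to use
#'   its default depth.
#' @param iterations Number of independent rarefactions averaged.
#' @param seed Integer seed; each sample gets its own derived RNG stream so
#'   results do not depend on sample order.
#' @return A `rarefaction_scheme` list.
#' @export
rarefaction_scheme <- function(depth = 1380, iterations = 100, seed = 1) {
  if (is.character(depth))
    depth <- switch(match.arg(depth, amplicon_levels()),
                    "16S" = 1380, "ITS1" = 751)
  stopifnot(depth > 0, iterations >= 1)
  structure(list(depth = as.integer(depth),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "rarefaction_scheme")
}

#' Rarefy one sample without replacement
#'
#' A single multivariate-hypergeometric draw of `depth` reads from the
#' sample's counts. The output always sums exactly to `depth` and its
#' support is contained in the input support.
#'
#' @param counts Non-negative integer vector for one sample.
#' @param depth Number of reads to draw; must not exceed the sample total
#'   (shallower samples are excluded from rarefied analyses, never
#'   zero-filled).
#' @return Integer vector of the same length and names.
#' @export
rarefy_once <- function(counts, depth) {
  total <- sum(counts)
  if (total < depth)
    abort(sprintf("Sample total %d is below rarefaction depth %d: exclude it.",
                  as.integer(total), as.integer(depth)))
  k <- length(counts)
  out <- integer(k)
  rem_total <- total
  rem_draw <- as.integer(depth)
  for (i in seq_len(k)) {
    if (rem_draw == 0L) break
    xi <- counts[i]
    rem_total <- rem_total - xi
    if (rem_total == 0) { out[i] <- rem_draw; rem_draw <- 0L; break }
    di <- rhyper(1, xi, rem_total, rem_draw)
    out[i] <- di
    rem_draw <- rem_draw - di
  }
  names(out) <- names(counts)
  out
}

#' Mean of repeated rarefactions
#'
#' Rarefies every sufficiently deep sample `iterations` times and returns
#' the entrywise mean table; each row of the mean table sums exactly to the
#' depth. Samples below the depth are excluded and listed in the
#' `excluded_samples` attribute.
#'
#' @param table An [asv_table] of integer counts.
#' @param scheme A [rarefaction_scheme()].
#' @return An [asv_table] of non-negative reals with attribute
#'   `excluded_samples`.
#' @export
repeat_rarefy_mean <- function(table, scheme) {
  totals <- rowSums(table)
  keep <- totals >= scheme$depth
  excluded <- rownames(table)[!keep]
  tab <- table[keep, , drop = FALSE]
  sub_seeds <- with_seed(scheme$seed,
                         sample.int(.Machine$integer.max, nrow(tab)))
  out <- matrix(0, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  for (s in seq_len(nrow(tab))) {
    x <- as.integer(round(unclass(tab)[s, ]))
    acc <- with_seed(sub_seeds[s], {
      a <- numeric(length(x))
      for (it in seq_len(scheme$iterations))
        a <- a + rarefy_once(x, scheme$depth)
      a
    })
    out[s, ] <- acc / scheme$iterations
  }
  res <- asv_table(out, amplicon = attr(table, "amplicon"))
  attr(res, "excluded_samples") <- excluded
  res
}

# ---------------------------------------------------------------------------
# alpha diversity
# ---------------------------------------------------------------------------

#' Alpha-diversity metrics for a single sample
#'
#' `shannon()` is the Shannon entropy \eqn{H = -\sum p_i \ln p_i} over taxa
#' with positive abundance (natural logarithm); `pielou()` is the evenness
#' \eqn{J = H / \ln S} with \eqn{S} the observed richness, undefined
#' (`NA`) when only one taxon is present; `richness()` counts taxa with
#' positive abundance.
#'
#' @param counts Non-negative abundance vector with a positive total.
#' @return A single number.
#' @export
shannon <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    abort("shannon() needs non-negative counts with positive total.")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
pielou <- function(counts) {
  s <- sum(counts > 0)
  if (s < 2) return(NA_real_)
  shannon(counts) / log(s)
}

#' @rdname shannon
#' @export
richness <- function(counts) sum(counts > 0)

# E x Ntip incidence: which tips descend from each edge
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, nn, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  inc <- desc[tree$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' Faith's phylogenetic diversity
#'
#' `faith_pd()` is the total branch length of the minimal subtree spanning
#' the present taxa and the root. `richness_corrected_pd()` divides PD by
#' the observed richness, a simple correction for the mechanical increase
#' of PD with the number of taxa; a null-model standardised effect size
#' (`faith_pd_ses()`) is available as the alternative correction.
#'
#' @param counts Named abundance vector; names must be tree tips.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param incidence Optional precomputed [edge-tip incidence] for repeated
#'   calls (internal speed-up).
#' @return A single number.
#' @export
faith_pd <- function(counts, tree, incidence = NULL) {
  present <- names(counts)[counts > 0]
  if (length(present) == 0) return(0)
  check_tips(tree, present)
  if (is.null(incidence)) incidence <- edge_tip_incidence(tree)
  on_path <- rowSums(incidence[, present, drop = FALSE]) > 0
  sum(tree$edge.length[on_path])
}

#' @rdname faith_pd
#' @export
richness_corrected_pd <- function(counts, tree, incidence = NULL) {
  s <- sum(counts > 0)
  if (s == 0) return(NA_real_)
  faith_pd(counts, tree, incidence) / s
}

#' @rdname faith_pd
#' @param n_null Number of null richness-preserving tip draws.
#' @param seed Seed for the null draws.
#' @export
faith_pd_ses <- function(counts, tree, n_null = 199, seed = 1,
                         incidence = NULL) {
  if (is.null(incidence)) incidence <- edge_tip_incidence(tree)
  obs <- faith_pd(counts, tree, incidence)
  s <- sum(counts > 0)
  if (s == 0) return(NA_real_)
  null_pd <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    tips <- sample(tree$tip.label, s)
    x <- setNames(rep(1, s), tips)
    faith_pd(x, tree, incidence)
  }, numeric(1)))
  (obs - mean(null_pd)) / (stats::sd(null_pd) + 1e-12)
}

#' Repeat-rarefied alpha diversity per sample
#'
#' For each sample deep enough for the scheme, rarefies `iterations` times
#' and averages richness, Shannon diversity, Pielou evenness and (when a
#' tree is supplied) Faith's PD and richness-corrected PD over iterations.
#'
#' @param table Raw integer [asv_table].
#' @param scheme A [rarefaction_scheme()].
#' @param tree Optional rooted phylogeny covering the table's ASVs
#'   (16S only in the motivating design).
#' @return Tibble with one row per retained sample; excluded samples are
#'   listed in the `excluded_samples` attribute.
#' @export
alpha_diversity <- function(table, scheme, tree = NULL) {
  totals <- rowSums(table)
  keep <- totals >= scheme$depth
  excluded <- rownames(table)[!keep]
  tab <- table[keep, , drop = FALSE]
  inc <- if (!is.null(tree)) {
    check_tips(tree, colnames(tab)[colSums(tab) > 0])
    edge_tip_incidence(tree)
  }
  sub_seeds <- with_seed(scheme$seed,
                         sample.int(.Machine$integer.max, nrow(tab)))
  rows <- vector("list", nrow(tab))
  for (s in seq_len(nrow(tab))) {
    x <- as.integer(round(unclass(tab)[s, ]))
    names(x) <- colnames(tab)
    m <- with_seed(sub_seeds[s], {
      acc <- matrix(NA_real_, scheme$iterations, 5)
      for (it in seq_len(scheme$iterations)) {
        r <- rarefy_once(x, scheme$depth)
        acc[it, 1] <- richness(r)
        acc[it, 2] <- shannon(r)
        acc[it, 3] <- pielou(r)
        if (!is.null(tree)) {
          acc[it, 4] <- faith_pd(r, tree, inc)
          acc[it, 5] <- acc[it, 4] / acc[it, 1]
        }
      }
      colMeans(acc)
    })
    rows[[s]] <- tibble::tibble(
      sample_id = rownames(tab)[s], richness = m[1], shannon = m[2],
      pielou = m[3], faith_pd = m[4], pd_richness_corrected = m[5])
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(tree))
    out <- dplyr::select(out, -"faith_pd", -"pd_richness_corrected")
  attr(out, "excluded_samples") <- excluded
  attr(out, "scheme") <- scheme
  out
}

# ---------------------------------------------------------------------------
# pairwise dissimilarities
# ---------------------------------------------------------------------------

#' Community dissimilarities between two samples
#'
#' `bray_curtis()` is \eqn{\sum |x_i - y_i| / \sum (x_i + y_i)};
#' `jaccard_binary()` is one minus the Jaccard similarity of the presence
#' sets; `weighted_unifrac()` is the unnormalised weighted UniFrac
#' \eqn{\sum_e b_e |p_e(x) - p_e(y)|}, where \eqn{p_e} is the fraction of a
#' sample's abundance descending from branch \eqn{e} (the `normalized` flag
#' divides by the maximum attainable value on the tree).
#'
#' @param x,y Equal-length non-negative abundance vectors (named by tree
#'   tips for UniFrac); at least one must have a positive total.
#' @return A single dissimilarity; `NA` when undefined (both totals zero).
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (tot <= 0) return(NA_real_)
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @export
jaccard_binary <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- x > 0; b <- y > 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  1 - sum(a & b) / u
}

#' @rdname bray_curtis
#' @param tree Rooted `phylo` tree whose tips cover the taxa.
#' @param normalized Divide by the tree-dependent maximum (default raw).
#' @param incidence Optional precomputed edge-tip incidence.
#' @export
weighted_unifrac <- function(x, y, tree, normalized = FALSE,
                             incidence = NULL) {
  stopifnot(length(x) == length(y))
  if (sum(x) <= 0 || sum(y) <= 0)
    abort("weighted_unifrac() needs positive totals in both samples.")
  nm <- names(x)
  if (is.null(nm)) abort("UniFrac input vectors must be named by taxon.")
  check_tips(tree, nm[x > 0 | y > 0])
  if (is.null(incidence)) incidence <- edge_tip_incidence(tree)
  px <- py <- numeric(ncol(incidence))
  names(px) <- names(py) <- colnames(incidence)
  px[nm] <- x / sum(x)
  py[nm] <- y / sum(y)
  pe_x <- as.numeric(incidence %*% px)
  pe_y <- as.numeric(incidence %*% py)
  d <- sum(tree$edge.length * abs(pe_x - pe_y))
  if (normalized) {
    dmax <- sum(tree$edge.length * (pe_x + pe_y))
    d <- if (dmax > 0) d / dmax else 0
  }
  d
}

# ---------------------------------------------------------------------------
# compositional transforms
# ---------------------------------------------------------------------------

#' Robust centred log-ratio transform
#'
#' Samples are first scaled to the dataset's median total (so that the
#' later Euclidean distances are comparable across depths), then each
#' sample's nonzero entries are mapped to \eqn{\ln v - \mathrm{mean}(\ln
#' v_{nonzero})}; zeros are left missing rather than imputed. Observed
#' entries of each transformed sample sum to zero.
#'
#' @param table Non-negative [asv_table]; every sample must have a positive
#'   total.
#' @return Numeric matrix with `NA` at the zero entries, carrying attribute
#'   `median_total`.
#' @export
rclr_transform <- function(table) {
  totals <- rowSums(table)
  if (any(totals <= 0))
    abort(paste0("Zero-total sample '",
                 rownames(table)[which(totals <= 0)[1]],
                 "' cannot be rCLR-transformed."))
  med <- median(totals)
  m <- unclass(table) * (med / totals)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (s in seq_len(nrow(m))) {
    nz <- m[s, ] > 0
    lv <- log(m[s, nz])
    out[s, nz] <- lv - mean(lv)
  }
  attr(out, "median_total") <- med
  out
}

#' Additive log-ratio transform against the spike reference
#'
#' Each count is expressed as the natural log of its ratio to the sample's
#' spike read count, making values comparable on an absolute scale across
#' samples. A pseudocount (default 1) replaces zero counts only.
#'
#' @param table Experimental [asv_table].
#' @param spike_counts Named vector (or `spikes` tibble) of per-sample
#'   spike reads; must be positive.
#' @param pseudocount Value substituted for zero counts before the log.
#' @return Numeric matrix of log-ratios.
#' @export
alr_by_spike <- function(table, spike_counts, pseudocount = 1) {
  if (is.data.frame(spike_counts))
    spike_counts <- setNames(spike_counts$spike_reads,
                             spike_counts$sample_id)
  sc <- spike_counts[rownames(table)]
  if (anyNA(sc) || any(sc <= 0))
    abort("alr_by_spike() needs a positive spike count for every sample.")
  m <- unclass(table)
  m[m == 0] <- pseudocount
  log(m / as.numeric(sc))
}

# ---------------------------------------------------------------------------
# distance matrices
# ---------------------------------------------------------------------------

#' All-pairs sample dissimilarity matrix
#'
#' Computes the chosen metric between every pair of samples. Bray-Curtis
#' and Jaccard apply to abundance tables; weighted UniFrac additionally
#' needs the phylogeny; Euclidean applies to log-ratio-transformed matrices
#' (Aitchison distance when applied to CLR output). For rCLR input
#' (a matrix with missing entries) only Euclidean is meaningful: it is
#' computed over pairwise-complete coordinates and rescaled by
#' \eqn{\sqrt{D / D_{complete}}} so sparser pairs stay comparable.
#'
#' @param x An [asv_table] or transformed numeric matrix (samples x
#'   features).
#' @param metric One of `"bray_curtis"`, `"jaccard"`,
#'   `"weighted_unifrac"`, `"euclidean"`.
#' @param tree Required for `weighted_unifrac`.
#' @param normalized Passed to [weighted_unifrac()].
#' @return A [dist_matrix].
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "jaccard",
                                          "weighted_unifrac", "euclidean"),
                            tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  m <- unclass(x)
  n <- nrow(m)
  has_na <- anyNA(m)
  if (has_na && metric != "euclidean")
    abort(paste0("Metric '", metric, "' is not defined on matrices with ",
                 "missing entries (rCLR output); use 'euclidean'."))
  if (metric == "weighted_unifrac" && is.null(tree))
    abort("weighted_unifrac needs a tree.")
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "euclidean") {
    if (!has_na) {
      out <- as.matrix(dist(m))
    } else {
      D <- ncol(m)
      obs <- !is.na(m)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        both <- obs[i, ] & obs[j, ]
        dc <- sum(both)
        if (dc == 0) abort(sprintf(
          "Samples '%s' and '%s' share no observed coordinates.",
          rownames(m)[i], rownames(m)[j]))
        d <- sqrt(sum((m[i, both] - m[j, both])^2)) * sqrt(D / dc)
        out[i, j] <- out[j, i] <- d
      }
    }
  } else if (metric == "weighted_unifrac") {
    check_tips(tree, colnames(m)[colSums(m) > 0])
    inc <- edge_tip_incidence(tree)
    p <- matrix(0, n, ncol(inc), dimnames = list(rownames(m),
                                                 colnames(inc)))
    p[, colnames(m)] <- m / rowSums(m)
    pe <- p %*% t(inc)                    # n x E edge loads
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sum(tree$edge.length * abs(pe[i, ] - pe[j, ]))
      if (normalized) {
        dmax <- sum(tree$edge.length * (pe[i, ] + pe[j, ]))
        d <- if (dmax > 0) d / dmax else 0
      }
      out[i, j] <- out[j, i] <- d
    }
  } else {
    f <- if (metric == "bray_curtis") bray_curtis else jaccard_binary
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- f(m[i, ], m[j, ])
    }
  }
  dist_matrix(out)
}
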