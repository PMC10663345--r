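test_that("Gower centring matches hand algebra and the Huygens identity", {
  d <- 0.8
  m <- matrix(c(0, d, d, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  G <- gower_center(dist_matrix(m))
  expect_equal(G, matrix(c(d^2 / 4, -d^2 / 4, -d^2 / 4, d^2 / 4), 2,
                         dimnames = dimnames(m)))

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(gower_center(dist_matrix(z))), matrix(0, 3, 3))

  for (seed in 1:5) {
    dm <- rand_dist(8, seed = 700 + seed)
    G <- gower_center(dm)
    d2 <- unclass(dm)^2
    expect_equal(sum(diag(G)), sum(d2[upper.tri(d2)]) / 8)
    expect_lt(max(abs(rowSums(G))), 1e-10)
  }
})

test_that("univariate pseudo-F equals classical one-way ANOVA F", {
  set.seed(21)
  g <- rep(c("a", "b", "c"), each = 7)
  y <- rnorm(21) + as.numeric(factor(g)) * 0.5
  md <- tibble::tibble(sample_id = paste0("s", 1:21), g = g)
  fit <- perm_anova_univariate(setNames(y, md$sample_id), md, ~ g,
                               n_perm = 99, seed = 2)
  expect_equal(fit$terms$pseudo_f, oneway_anova_f(y, g), tolerance = 1e-10)
  # SS decomposition is the classical one
  gm <- mean(y)
  expect_equal(fit$total_ss, sum((y - gm)^2), tolerance = 1e-10)
})

test_that("exact permutation p-values equal exhaustive enumeration", {
  set.seed(5)
  y <- rnorm(6)
  g <- c("a", "a", "a", "b", "b", "b")
  md <- tibble::tibble(sample_id = paste0("s", 1:6), g = g)
  fit <- perm_anova_univariate(setNames(y, md$sample_id), md, ~ g,
                               n_perm = "exact")
  f0 <- oneway_anova_f(y, g)
  splits <- combn(6, 3)
  fs <- apply(splits, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"
    oneway_anova_f(y, gg)
  })
  expect_equal(fit$terms$p_value, mean(fs >= f0 - 1e-8))

  # multivariate case: Bray-Curtis distances of a small table
  tab <- rand_table(6, 8, seed = 55)
  dm <- distance_matrix(tab, "bray_curtis")
  md2 <- tibble::tibble(sample_id = rownames(tab), g = g)
  fit2 <- permanova(dm, md2, ~ g, n_perm = "exact")
  # oracle: recompute pseudo-F from first principles for every split
  pseudo_f <- function(D2, grp) {
    n <- nrow(D2)
    tot <- sum(D2[upper.tri(D2)]) / n
    ssw <- 0
    for (lev in unique(grp)) {
      idx <- which(grp == lev)
      sub <- D2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((tot - ssw) / (length(unique(grp)) - 1)) / (ssw / (n - length(unique(grp))))
  }
  D2 <- unclass(dm)^2
  f0m <- pseudo_f(D2, g)
  expect_equal(fit2$terms$pseudo_f, f0m, tolerance = 1e-10)
  fsm <- apply(splits, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"
    pseudo_f(D2, gg)
  })
  expect_equal(fit2$terms$p_value, mean(fsm >= f0m - 1e-8))
})

test_that("sequential SS partitions agree with vegan::adonis2", {
  set.seed(31)
  n <- 30
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    A = sample(c("a", "b", "c"), n, TRUE),
    B = sample(c("x", "y"), n, TRUE),
    blk = sample(c("r1", "r2"), n, TRUE))
  tab <- rand_table(n, 12, seed = 32)
  rownames(tab) <- md$sample_id
  tab <- asv_table(unclass(tab))
  dm <- distance_matrix(tab, "bray_curtis")
  fit <- permanova(dm, md, ~ blk + A * B, n_perm = 49, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ blk + A * B,
                        data = as.data.frame(md), permutations = 49,
                        by = "terms")
  k <- nrow(fit$terms)
  expect_equal(fit$terms$ss, ref$SumOfSqs[1:k], tolerance = 1e-10)
  expect_equal(fit$terms$df, ref$Df[1:k])
  expect_equal(fit$terms$pseudo_f, ref$F[1:k], tolerance = 1e-10)
  expect_equal(fit$terms$r_squared, ref$R2[1:k], tolerance = 1e-10)
  expect_equal(fit$residual_ss, ref$SumOfSqs[k + 1], tolerance = 1e-10)
  # conservation of the SS decomposition
  expect_equal(sum(fit$terms$ss) + fit$residual_ss, fit$total_ss,
               tolerance = 1e-8 * fit$total_ss)
})

test_that("marginal SS agrees with vegan::adonis2 by margin", {
  set.seed(35)
  n <- 24
  dm <- distance_matrix(rand_table(n, 10, seed = 36), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       A = sample(c("a", "b"), n, TRUE),
                       B = sample(c("x", "y", "z"), n, TRUE))
  fit <- permanova(dm, md, ~ A + B, n_perm = 49, seed = 1, ss = "margin")
  ref <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ A + B,
                        data = as.data.frame(md), permutations = 49,
                        by = "margin")
  expect_equal(fit$terms$ss, ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(fit$terms$pseudo_f, ref$F[1:2], tolerance = 1e-10)
})

test_that("permanova is invariant to simultaneous sample reordering", {
  dm <- distance_matrix(rand_table(12, 9, seed = 41), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       g = rep(c("a", "b", "c"), 4))
  fit1 <- permanova(dm, md, ~ g, n_perm = 99, seed = 7)
  ord <- c(5, 1, 12, 3, 8, 2, 10, 6, 4, 11, 7, 9)
  dm2 <- dist_matrix(unclass(dm)[ord, ord])
  fit2 <- permanova(dm2, md[ord, ], ~ g, n_perm = 99, seed = 7)
  expect_equal(fit1$terms$ss, fit2$terms$ss, tolerance = 1e-10)
  expect_equal(fit1$terms$pseudo_f, fit2$terms$pseudo_f, tolerance = 1e-10)
})

test_that("perfect group separation yields R-squared 1 at the smallest p", {
  m <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  m[1:3, 4:6] <- 1; m[4:6, 1:3] <- 1
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       g = rep(c("a", "b"), each = 3))
  fit <- permanova(dist_matrix(m), md, ~ g, n_perm = "exact")
  expect_equal(fit$terms$r_squared, 1, tolerance = 1e-10)
  # the permutation minimum: only relabelings preserving the partition tie
  # with the observed F (2 * 3! * 3! of the 720 permutations)
  expect_equal(fit$terms$p_value, 72 / 720, tolerance = 1e-12)

  # constant response: no variation, no test
  mdc <- tibble::tibble(sample_id = paste0("s", 1:6),
                        g = rep(c("a", "b"), 3))
  fitc <- perm_anova_univariate(setNames(rep(2, 6), mdc$sample_id), mdc,
                                ~ g, n_perm = 49)
  expect_equal(fitc$total_ss, 0)
  expect_true(is.na(fitc$terms$p_value))
})

test_that("permutation strata keep exchanges within blocks", {
  set.seed(61)
  dm <- distance_matrix(rand_table(16, 10, seed = 62), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       g = rep(c("a", "b"), 8),
                       blk = rep(c("u", "v"), each = 8))
  fit <- permanova(dm, md, ~ g, n_perm = 99, seed = 3, strata = "blk")
  expect_equal(fit$permutation, "within blk")
  perms <- endostat:::make_permutations(16, 50, 9, strata = md$blk)
  for (b in 1:50) {
    p <- perms[, b]
    expect_true(all(md$blk[p] == md$blk))
  }
})

test_that("pairwise PERMANOVA applies the Benjamini-Hochberg step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(71)
  dm <- distance_matrix(rand_table(18, 10, seed = 72), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       g = rep(c("a", "b", "c"), each = 6),
                       stage = rep("Vegetative", 18))
  pw <- permanova_pairwise(dm, md, "g", n_perm = 99, seed = 4)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, method = "BH"))

  # two levels: adjusted equals raw
  pw2 <- permanova_pairwise(dm, md, "g", levels = c("a", "b"),
                            n_perm = 99, seed = 4)
  expect_equal(pw2$p_adjusted, pw2$p_value)

  # a level with < 2 samples is skipped, not fatal
  md3 <- md; md3$g[md3$g == "c"] <- c("c", rep("d", 5))
  pw3 <- permanova_pairwise(dm, md3, "g", n_perm = 49, seed = 4)
  expect_true(any(grepl("c", attr(pw3, "skipped"))))
})

test_that("PCoA reconstructs distances, with imaginary correction when needed", {
  # planar configuration: exact Euclidean embedding
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  m <- as.matrix(dist(pts))
  rownames(m) <- colnames(m) <- paste0("s", 1:3)
  emb <- pcoa_embed(dist_matrix(m))
  rec <- as.matrix(dist(emb$real))
  expect_lt(max(abs(rec - m)), 1e-8)
  expect_equal(ncol(emb$imaginary), 0)

  # collinear points: a single dominant positive axis
  line <- as.matrix(dist(matrix(c(0, 1, 2.5, 4), 4)))
  rownames(line) <- colnames(line) <- paste0("s", 1:4)
  embl <- pcoa_embed(dist_matrix(line))
  expect_equal(ncol(embl$real), 1)

  # non-Euclidean (semi-metric) input: corrected reconstruction
  tab <- rand_table(10, 6, seed = 81, lambda = 2)
  tab <- tab[rowSums(tab) > 0, ]
  dmb <- distance_matrix(tab, "bray_curtis")
  embb <- pcoa_embed(dmb)
  expect_gt(ncol(embb$imaginary), 0)
  n <- nrow(dmb)
  rec2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dr2 <- sum((embb$real[i, ] - embb$real[j, ])^2)
    di2 <- sum((embb$imaginary[i, ] - embb$imaginary[j, ])^2)
    rec2[i, j] <- dr2 - di2
  }
  expect_lt(max(abs(rec2 - unclass(dmb)^2)), 1e-6)
})

test_that("PERMDISP distances match original-space geometry for Euclidean data", {
  set.seed(91)
  X <- matrix(rnorm(20 * 4), 20)
  rownames(X) <- sprintf("s%02d", 1:20)
  g <- rep(c("a", "b"), each = 10)
  dm <- dist_matrix(as.matrix(dist(X)))
  pd <- permdisp(dm, setNames(g, rownames(X)), center = "centroid",
                 n_perm = 99, seed = 2)
  direct <- numeric(20)
  for (lev in c("a", "b")) {
    idx <- g == lev
    ctr <- colMeans(X[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(X[idx, ], 2, ctr)^2))
  }
  expect_lt(max(abs(pd$distances$distance - direct)), 1e-8)

  # spatial-median version agrees with an independent optimiser
  pdm <- permdisp(dm, setNames(g, rownames(X)), n_perm = 99, seed = 2)
  for (lev in c("a", "b")) {
    idx <- g == lev
    obj <- function(v) sum(sqrt(rowSums(sweep(X[idx, ], 2, v)^2)))
    opt <- optim(colMeans(X[idx, ]), obj, method = "BFGS",
                 control = list(reltol = 1e-12))
    ref <- sqrt(rowSums(sweep(X[idx, ], 2, opt$par)^2))
    expect_lt(max(abs(pdm$distances$distance[idx] - ref)), 1e-5)
  }
})

test_that("PERMDISP agrees with vegan::betadisper and handles degeneracy", {
  tab <- rand_table(16, 10, seed = 95)
  dm <- distance_matrix(tab, "bray_curtis")
  g <- rep(c("a", "b"), each = 8)
  names(g) <- rownames(tab)
  pd <- permdisp(dm, g, center = "centroid", n_perm = 99, seed = 5)
  bd <- vegan::betadisper(stats::as.dist(unclass(dm)), g, type = "centroid")
  expect_equal(pd$distances$distance, unname(bd$distances),
               tolerance = 1e-8)
  f_ref <- anova(bd)$F[1]
  expect_equal(pd$terms$pseudo_f, f_ref, tolerance = 1e-8)

  # all points coincident: no dispersion to test
  z <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  pdz <- permdisp(dist_matrix(z), setNames(rep(c("a", "b"), 2),
                                           paste0("s", 1:4)), n_perm = 49)
  expect_true(is.na(pdz$terms$pseudo_f))
  expect_true(is.na(pdz$terms$p_value))

  expect_error(permdisp(dm, setNames(c("a", rep("b", 15)), rownames(tab))),
               "fewer than 2")
})

test_that("rank-deficient terms confounded with earlier ones get zero df", {
  dm <- distance_matrix(rand_table(8, 6, seed = 99), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       g = rep(c("a", "b"), each = 4),
                       g2 = rep(c("a", "b"), each = 4))  # alias of g
  fit <- permanova(dm, md, ~ g + g2, n_perm = 49, seed = 1)
  expect_equal(fit$terms$df, c(1L, 0L))
  expect_true(is.na(fit$terms$p_value[2]))
})

test_that("tidy and glance expose the variance partition", {
  dm <- distance_matrix(rand_table(9, 6, seed = 101), "bray_curtis")
  md <- tibble::tibble(sample_id = rownames(dm),
                       g = rep(c("a", "b", "c"), 3))
  fit <- permanova(dm, md, ~ g, n_perm = 49, seed = 1)
  td <- tidy(fit, include_residual = TRUE)
  expect_equal(td$term, c("g", "Residual", "Total"))
  expect_equal(sum(td$ss[1:2]), td$ss[3], tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$n_perm, 49)
})
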