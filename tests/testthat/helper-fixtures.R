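# Small deterministic fixtures built in code.

rand_table <- function(n, k, seed, lambda = 20, amplicon = "16S") {
  set.seed(seed)
  m <- matrix(rpois(n * k, lambda), n, k,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("a%03d", seq_len(k))))
  asv_table(m, amplicon = amplicon)
}

rand_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 3), n)
  m <- as.matrix(dist(x))
  rownames(m) <- colnames(m) <- sprintf("s%02d", seq_len(n))
  dist_matrix(m)
}

# a valid plant metadata tibble covering several stages/tissues
demo_metadata <- function() {
  rows <- list()
  id <- 0
  for (stg in c("Vegetative", "RipeSiliques")) {
    for (g in c("WT", "lore")) {
      for (p in 1:2) {
        pid <- paste0(stg, "_", g, "_", p)
        for (tis in stage_tissues()[[stg]]) {
          id <- id + 1
          rows[[id]] <- tibble::tibble(
            sample_id = sprintf("m%03d", id), plant_id = pid,
            genotype = g, tissue = tis, stage = stg,
            run = "run1", plate = "run1_p1", amplicon = "16S")
        }
      }
    }
  }
  validate_metadata(dplyr::bind_rows(rows))
}

# classical one-way ANOVA F, computed from first principles (independent of
# the package and of stats::lm)
oneway_anova_f <- function(y, g) {
  g <- as.character(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  k <- length(unique(g))
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}
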