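# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {                     # all shapes vanishingly small
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / s
}

#' Configuration of the synthetic field-survey generator
#'
#' Defines the study design and stochastic model from which synthetic ASV
#' tables are drawn. The default design mirrors the harvest plan of the
#' field experiment: five genotypes, four developmental stages with their
#' stage-specific tissue sets, eight plants per genotype per stage (eighteen
#' at the Unripe Siliques stage), sequencing depth log-normal so that sample
#' depth spans roughly three orders of magnitude, and a handful of dedicated
#' spike-in ASV columns whose per-sample read fraction is drawn within the
#' quantitation window.
#'
#' Counts follow a Dirichlet-multinomial: each sample's expected
#' log-composition is a sum of a sparse baseline, tissue and stage effects,
#' an optional genotype log-fold effect restricted to designated taxa in
#' designated tissue-by-stage cells, a per-plant random effect shared across
#' that plant's tissues, and batch (run and plate) effects; overdispersion
#' around the resulting composition is governed by `dm_concentration`.
#'
#' @param n_plants Named integer vector: plants per genotype at each stage.
#' @param genotypes,stages Subsets of the design to simulate.
#' @param tissues Optional tissue restriction (intersected with the tissues
#'   present at each stage).
#' @param amplicon `"16S"` (a random phylogeny is attached) or `"ITS1"`.
#' @param n_asvs,n_spike_asvs Number of experimental and spike ASVs.
#' @param baseline_concentration Symmetric Dirichlet concentration of the
#'   baseline composition (small values give realistically uneven baselines).
#' @param tissue_effect_sd,stage_effect_sd SD of per-taxon log-scale tissue
#'   and stage effects.
#' @param genotype_effect Log-fold change applied to affected taxa for
#'   `affected_genotype` within `affected_cells` (0 = null design).
#' @param affected_fraction Fraction of taxa carrying the genotype effect.
#' @param affected_genotype Genotype carrying the planted effect.
#' @param affected_cells Data frame with columns `tissue`, `stage` naming
#'   the cells where the effect is active.
#' @param plant_effect_sd SD of the per-plant random effect (shared by all
#'   tissues of a plant; induces within-individual correlation).
#' @param run_effect_sd,plate_effect_sd Batch effect SDs; plates are nested
#'   in runs.
#' @param n_runs,n_plates_per_run Batch structure.
#' @param depth_logmean,depth_logsd Log-normal sequencing-depth parameters
#'   (defaults: median 5000 reads, `sdlog` 1.2).
#' @param spike_frac_range Per-sample spike read fraction is uniform on this
#'   range.
#' @param dm_concentration Dirichlet-multinomial precision; larger is closer
#'   to multinomial sampling.
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plants = c(Vegetative = 8, Flowering = 8,
                                    UnripeSiliques = 18, RipeSiliques = 8),
                       genotypes = genotype_levels(),
                       stages = stage_levels(),
                       tissues = NULL,
                       amplicon = "16S",
                       n_asvs = 150,
                       n_spike_asvs = 3,
                       baseline_concentration = 0.5,
                       tissue_effect_sd = 1,
                       stage_effect_sd = 0.5,
                       genotype_effect = 0,
                       affected_fraction = 0.1,
                       affected_genotype = "lore",
                       affected_cells = data.frame(
                         tissue = "mature_silique", stage = "RipeSiliques"),
                       plant_effect_sd = 0.5,
                       run_effect_sd = 0.2,
                       plate_effect_sd = 0.2,
                       n_runs = 2,
                       n_plates_per_run = 2,
                       depth_logmean = log(5000),
                       depth_logsd = 1.2,
                       spike_frac_range = c(0.2, 0.8),
                       dm_concentration = 50,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(stages %in% stage_levels()),
            all(genotypes %in% genotype_levels()))
  if (!is.null(tissues) && !all(tissues %in% tissue_levels()))
    abort("Unknown tissue in sim_config.")
  sds <- c(tissue_effect_sd, stage_effect_sd, plant_effect_sd,
           run_effect_sd, plate_effect_sd, depth_logsd)
  if (any(sds < 0)) abort("Effect scales must be non-negative.")
  if (affected_fraction < 0 || affected_fraction > 1)
    abort("affected_fraction must lie in [0, 1].")
  if (length(spike_frac_range) != 2 ||
      spike_frac_range[1] > spike_frac_range[2] ||
      spike_frac_range[1] <= 0 || spike_frac_range[2] >= 1)
    abort("spike_frac_range must be an increasing pair inside (0, 1).")
  if (n_asvs < 2 || n_spike_asvs < 1)
    abort("Need at least 2 experimental ASVs and 1 spike ASV.")
  if (dm_concentration <= 0) abort("dm_concentration must be positive.")
  structure(cfg, class = "sim_config")
}

# Fixed-effect parameter draws; consumed first inside the seeded stream so
# expected_cell_composition() reproduces them independently of the rest of
# the simulation.
draw_sim_params <- function(config) {
  K <- config$n_asvs
  # infinite concentration = the symmetric (uniform) baseline limit
  baseline <- if (is.infinite(config$baseline_concentration))
    rep(1 / K, K) else rdirichlet1(rep(config$baseline_concentration, K))
  baseline <- pmax(baseline, 1e-12)
  tiss_all <- setdiff(tissue_levels(), "soil")
  tissue_eff <- matrix(rnorm(length(tiss_all) * K, 0, config$tissue_effect_sd),
                       nrow = length(tiss_all),
                       dimnames = list(tiss_all, NULL))
  stage_eff <- matrix(rnorm(length(stage_levels()) * K, 0,
                            config$stage_effect_sd),
                      nrow = length(stage_levels()),
                      dimnames = list(stage_levels(), NULL))
  n_aff <- round(config$affected_fraction * K)
  affected <- if (n_aff > 0) sort(sample.int(K, n_aff)) else integer(0)
  geno_delta <- numeric(K)
  geno_delta[affected] <- config$genotype_effect
  list(log_baseline = log(baseline), tissue_eff = tissue_eff,
       stage_eff = stage_eff, geno_delta = geno_delta,
       affected_taxa = affected)
}

cell_log_mean <- function(config, params, genotype, tissue, stage) {
  eta <- params$log_baseline + params$tissue_eff[tissue, ] +
    params$stage_eff[stage, ]
  hit <- genotype == config$affected_genotype &&
    any(config$affected_cells$tissue == tissue &
          config$affected_cells$stage == stage)
  if (hit) eta <- eta + params$geno_delta
  eta
}

#' Expected composition of one design cell
#'
#' Closed-form generator mean used to verify the simulator: the softmax of
#' the configured fixed log-effects (baseline + tissue + stage + genotype,
#' the latter only in the affected cells), i.e. the cell composition at zero
#' realised plant, batch and sampling noise.
#'
#' @param config A [sim_config].
#' @param genotype,tissue,stage The design cell.
#' @return Probability vector over the experimental ASVs (sums to 1).
#' @export
expected_cell_composition <- function(config, genotype, tissue, stage) {
  if (!stage %in% config$stages || !genotype %in% config$genotypes)
    abort("Cell outside the configured design.")
  avail <- stage_tissues()[[stage]]
  if (!is.null(config$tissues)) avail <- intersect(avail, config$tissues)
  if (!tissue %in% avail)
    abort(sprintf("Tissue '%s' is not present at stage '%s' in this design.",
                  tissue, stage))
  params <- with_seed(config$seed, draw_sim_params(config))
  eta <- cell_log_mean(config, params, genotype, tissue, stage)
  p <- exp(eta - max(eta))
  p / sum(p)
}

#' Simulate a complete synthetic field survey
#'
#' Draws an ASV count table, sample metadata, spike registry and (for 16S)
#' a random rooted phylogeny with exponential branch lengths, under the
#' generative model described in [sim_config()]. One sample is produced per
#' plant-tissue combination, tissues follow the harvest design of each
#' developmental stage, spike reads are appended as dedicated ASV columns to
#' reach a per-sample spike fraction drawn within the configured window, and
#' all output is reproducible from the configuration seed.
#'
#' @param config A [sim_config].
#' @return A list of class `sim_dataset` with elements `table`
#'   ([asv_table]), `metadata` (tibble), `registry` ([spike_registry]),
#'   `tree` (`phylo` or `NULL` for ITS1), and `params` (the realised
#'   fixed-effect draws).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    params <- draw_sim_params(config)
    K <- config$n_asvs
    asv_ids <- sprintf("ASV_%04d", seq_len(K))
    spike_ids <- sprintf("SPIKE_%02d", seq_len(config$n_spike_asvs))

    # design expansion: one row per (plant, tissue)
    rows <- list()
    for (stg in config$stages) {
      tiss <- stage_tissues()[[stg]]
      if (!is.null(config$tissues)) tiss <- intersect(tiss, config$tissues)
      if (length(tiss) == 0) next
      np <- config$n_plants[[stg]]
      for (g in config$genotypes) {
        for (i in seq_len(np)) {
          pid <- sprintf("%s_%s_%02d", stg, g, i)
          rows[[length(rows) + 1]] <- tibble::tibble(
            plant_id = pid, genotype = g, tissue = tiss, stage = stg)
        }
      }
    }
    design <- dplyr::bind_rows(rows)
    n <- nrow(design)
    if (n == 0) abort("Empty design: no stage/tissue cells to simulate.")
    design$sample_id <- sprintf("S%04d", seq_len(n))

    runs <- sprintf("run%d", seq_len(config$n_runs))
    design$run <- sample(runs, n, replace = TRUE)
    design$plate <- paste0(
      design$run, "_plate",
      sample.int(config$n_plates_per_run, n, replace = TRUE))
    design$amplicon <- config$amplicon

    plant_ids <- unique(design$plant_id)
    plant_eff <- matrix(rnorm(length(plant_ids) * K, 0,
                              config$plant_effect_sd),
                        nrow = length(plant_ids),
                        dimnames = list(plant_ids, NULL))
    run_eff <- matrix(rnorm(config$n_runs * K, 0, config$run_effect_sd),
                      nrow = config$n_runs, dimnames = list(runs, NULL))
    plates <- sort(unique(design$plate))
    plate_eff <- matrix(rnorm(length(plates) * K, 0, config$plate_effect_sd),
                        nrow = length(plates),
                        dimnames = list(plates, NULL))

    counts <- matrix(0, n, K + config$n_spike_asvs,
                     dimnames = list(design$sample_id,
                                     c(asv_ids, spike_ids)))
    lo <- config$spike_frac_range[1]; hi <- config$spike_frac_range[2]
    for (s in seq_len(n)) {
      eta <- cell_log_mean(config, params, design$genotype[s],
                           design$tissue[s], design$stage[s]) +
        plant_eff[design$plant_id[s], ] +
        run_eff[design$run[s], ] +
        plate_eff[design$plate[s], ]
      p <- exp(eta - max(eta)); p <- p / sum(p)
      depth <- max(2L, as.integer(round(rlnorm(1, config$depth_logmean,
                                               config$depth_logsd))))
      f <- runif(1, lo, hi)
      n_spike <- as.integer(round(depth * f))
      n_spike <- min(max(n_spike, 1L), depth - 1L)
      n_exp <- depth - n_spike
      q <- rdirichlet1(config$dm_concentration * p)
      counts[s, seq_len(K)] <- rmultinom(1, n_exp, q)
      counts[s, K + seq_len(config$n_spike_asvs)] <-
        rmultinom(1, n_spike, rep(1, config$n_spike_asvs))
    }

    tree <- NULL
    if (config$amplicon == "16S") {
      tree <- ape::rtree(K, tip.label = sample(asv_ids))
      tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
      tree <- validate_phylo_tree(tree)
    }

    metadata <- validate_metadata(
      design[, c("sample_id", "plant_id", "genotype", "tissue", "stage",
                 "run", "plate", "amplicon")])

    structure(
      list(table = asv_table(counts, amplicon = config$amplicon),
           metadata = metadata,
           registry = spike_registry(spike_ids, amplicon = config$amplicon),
           tree = tree,
           params = params),
      class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d samples, %d ASVs (%s)%s\n",
              nrow(x$table), ncol(x$table), attr(x$table, "amplicon"),
              if (is.null(x$tree)) "" else ", with tree"))
  invisible(x)
}
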