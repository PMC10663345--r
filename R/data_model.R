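#' @importFrom rlang .data abort warn
#' @importFrom stats median rnorm rlnorm rhyper rgamma rexp runif rmultinom
#' @importFrom stats setNames var pf p.adjust model.matrix terms as.formula dist
#' @importFrom utils head read.delim write.table combn
NULL

#' Design factor levels of the field experiment
#'
#' The experimental design crosses five *Arabidopsis thaliana* genotypes
#' (wild type and four single pattern-recognition-receptor knockouts) with
#' plant tissues and developmental stages; bulk soil is sampled alongside.
#' Not every tissue exists at every stage: vegetative plants carry only roots
#' and rosettes, and reproductive tissues appear as the plant matures.
#'
#' @return `stage_tissues()` returns a named list mapping each developmental
#'   stage to the plant tissues present at that stage. The constants are
#'   character vectors of the admissible factor levels.
#' @export
stage_tissues <- function() {
  list(
    Vegetative     = c("root", "rosette"),
    Flowering      = c("root", "rosette", "stem", "cauline_leaf", "flower"),
    UnripeSiliques = c("root", "rosette", "stem", "cauline_leaf", "flower",
                       "immature_silique"),
    RipeSiliques   = c("root", "rosette", "stem", "cauline_leaf", "flower",
                       "immature_silique", "mature_silique")
  )
}

#' @rdname stage_tissues
#' @export
genotype_levels <- function() c("WT", "efr", "fls2", "lore", "lyk4")

#' @rdname stage_tissues
#' @export
tissue_levels <- function() {
  c("root", "rosette", "stem", "cauline_leaf", "flower",
    "immature_silique", "mature_silique", "soil")
}

#' @rdname stage_tissues
#' @export
stage_levels <- function() names(stage_tissues())

#' @rdname stage_tissues
#' @export
amplicon_levels <- function() c("16S", "ITS1")

# ---------------------------------------------------------------------------
# asv_table: samples x ASVs abundance matrix
# ---------------------------------------------------------------------------

#' Construct a sample-by-ASV abundance table
#'
#' An `asv_table` is a numeric matrix with samples as rows and amplicon
#' sequence variants (ASVs) as columns, plus the amplicon it was derived
#' from. Raw tables hold integer read counts; scaled or repeat-rarefied
#' tables hold non-negative reals.
#'
#' @param counts Numeric matrix, samples x ASVs, with unique row and column
#'   names and no negative entries.
#' @param amplicon Marker gene, `"16S"` or `"ITS1"`.
#' @return An object of class `asv_table` (a matrix with an `amplicon`
#'   attribute).
#' @export
asv_table <- function(counts, amplicon = "16S") {
  counts <- as.matrix(counts)
  amplicon <- match.arg(amplicon, amplicon_levels())
  validate_asv_counts(counts)
  structure(counts, amplicon = amplicon,
            class = c("asv_table", class(counts)))
}

validate_asv_counts <- function(counts) {
  if (!is.numeric(counts)) abort("ASV table body must be numeric.")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("ASV table needs sample (row) and ASV (column) identifiers.")
  if (anyDuplicated(rownames(counts)))
    abort(paste0("Duplicate sample identifier: ",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    abort(paste0("Duplicate ASV identifier: ",
                 colnames(counts)[duplicated(colnames(counts))][1]))
  if (anyNA(counts)) abort("ASV table contains missing values.")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    abort(sprintf("Negative abundance at sample '%s', ASV '%s'.",
                  rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  invisible(counts)
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs (%s)\n",
              nrow(x), ncol(x), attr(x, "amplicon")))
  total <- sum(x)
  cat(sprintf("  total abundance %.6g; %.1f%% zero entries\n",
              total, 100 * mean(x == 0)))
  invisible(x)
}

#' @export
`[.asv_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, amplicon = attr(x, "amplicon"),
                     class = c("asv_table", "matrix", "array"))
  out
}

#' @importFrom tibble as_tibble
#' @method as_tibble asv_table
#' @export
as_tibble.asv_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "sample_id")
}

#' Read or write a sample-by-ASV table
#'
#' Tab-separated tables (first column = row identifiers) and BIOM files are
#' supported. External TSV tables come in both orientations; by default the
#' reader keeps rows as samples, but when `sample_ids` (e.g. from the
#' metadata) are supplied it auto-detects orientation by testing which margin
#' matches the known sample identifiers, and `orientation` overrides.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`; `"auto"` decides from the extension.
#' @param orientation `"auto"`, `"samples_rows"` or `"asvs_rows"`.
#' @param sample_ids Optional character vector of known sample identifiers
#'   used by orientation auto-detection.
#' @param amplicon Marker gene label to attach.
#' @return An [asv_table].
#' @export
read_asv_table <- function(path, format = c("auto", "tsv", "biom"),
                           orientation = c("auto", "samples_rows", "asvs_rows"),
                           sample_ids = NULL, amplicon = "16S") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      abort("Reading BIOM files requires the 'biomformat' package.")
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    # biom convention: observations (ASVs) x samples
    m <- t(m)
  } else {
    df <- read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  flip <- switch(orientation,
    samples_rows = FALSE,
    asvs_rows    = TRUE,
    auto = {
      if (is.null(sample_ids)) FALSE
      else {
        hit_rows <- mean(rownames(m) %in% sample_ids)
        hit_cols <- mean(colnames(m) %in% sample_ids)
        hit_cols > hit_rows
      }
    })
  if (flip) m <- t(m)
  asv_table(m, amplicon = amplicon)
}

#' @rdname read_asv_table
#' @param table An [asv_table] to write (samples as rows).
#' @export
write_asv_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample metadata
# ---------------------------------------------------------------------------

#' Read and validate per-sample design metadata
#'
#' The metadata table carries the design factors of every sequenced sample:
#' the plant it came from, genotype, tissue, developmental stage, the MiSeq
#' run and the extraction/PCR plate (the batch structure), and the amplicon.
#' Validation enforces the factor enumerations, the stage/tissue
#' availability of the harvest design (vegetative plants have only roots and
#' rosettes, etc.), uniqueness of `(plant_id, tissue)` within an amplicon,
#' and that every non-soil sample names its plant. Bulk-soil rows (tissue
#' `"soil"`) may leave `plant_id`, `genotype` and `stage` empty; they are
#' flagged via the `is_soil` column and excluded from plant-only analyses.
#'
#' @param path Tab-separated file with columns `sample_id`, `plant_id`,
#'   `genotype`, `tissue`, `stage`, `run`, `plate`, `amplicon`.
#' @return A validated tibble with an additional logical `is_soil` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- read.delim(path, colClasses = "character")
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata A data frame to validate in place of reading a file.
#' @export
validate_metadata <- function(metadata) {
  req <- c("sample_id", "plant_id", "genotype", "tissue", "stage",
           "run", "plate", "amplicon")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    abort(paste0("Metadata lacks column(s): ", paste(miss, collapse = ", ")))
  md <- tibble::as_tibble(metadata)
  md$plant_id[!is.na(md$plant_id) & md$plant_id == ""] <- NA_character_
  if (anyDuplicated(md$sample_id))
    abort(paste0("Duplicate sample_id: ",
                 md$sample_id[duplicated(md$sample_id)][1]))
  md$is_soil <- md$tissue == "soil"
  bad <- !md$tissue %in% tissue_levels()
  if (any(bad))
    abort(paste0("Unknown tissue '", md$tissue[bad][1], "' in sample ",
                 md$sample_id[bad][1]))
  bad <- !md$amplicon %in% amplicon_levels()
  if (any(bad))
    abort(paste0("Unknown amplicon '", md$amplicon[bad][1], "' in sample ",
                 md$sample_id[bad][1]))
  plant <- !md$is_soil
  bad <- plant & !md$genotype %in% genotype_levels()
  if (any(bad))
    abort(paste0("Unknown genotype '", md$genotype[bad][1], "' in sample ",
                 md$sample_id[bad][1]))
  bad <- plant & !md$stage %in% stage_levels()
  if (any(bad))
    abort(paste0("Unknown stage '", md$stage[bad][1], "' in sample ",
                 md$sample_id[bad][1]))
  bad <- plant & is.na(md$plant_id)
  if (any(bad))
    abort(paste0("Non-soil sample without plant_id: ", md$sample_id[bad][1]))
  # tissue must exist at the plant's developmental stage
  st <- stage_tissues()
  ok <- mapply(function(tis, stg) tis %in% st[[stg]],
               md$tissue[plant], md$stage[plant])
  if (any(!ok)) {
    i <- which(plant)[which(!ok)[1]]
    abort(sprintf(
      "Sample %s: tissue '%s' does not exist at stage '%s'.",
      md$sample_id[i], md$tissue[i], md$stage[i]))
  }
  key <- paste(md$plant_id[plant], md$tissue[plant], md$amplicon[plant])
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(paste0("Duplicate (plant_id, tissue) pair: ", d))
  }
  md
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata[setdiff(names(metadata), "is_soil")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Spike registry
# ---------------------------------------------------------------------------

#' Registry of synthetic spike-in ASVs
#'
#' Spike-ins are synthetic DNA sequences of known quantity co-amplified with
#' the marker gene; their ASV identifiers are recorded per amplicon so the
#' pipeline can separate spike reads from experimental reads and convert the
#' latter to an absolute scale.
#'
#' @param spike_ids Character vector of ASV identifiers that are spikes.
#' @param amplicon Marker gene the registry applies to.
#' @return An object of class `spike_registry`.
#' @export
spike_registry <- function(spike_ids, amplicon = "16S") {
  spike_ids <- as.character(spike_ids)
  if (anyDuplicated(spike_ids)) abort("Duplicate spike ASV identifier.")
  structure(list(spike_ids = spike_ids,
                 amplicon = match.arg(amplicon, amplicon_levels())),
            class = "spike_registry")
}

#' @export
print.spike_registry <- function(x, ...) {
  cat(sprintf("<spike_registry> %d spike ASVs (%s)\n",
              length(x$spike_ids), x$amplicon))
  invisible(x)
}

#' @rdname spike_registry
#' @param path One spike ASV identifier per line.
#' @export
read_spike_registry <- function(path, amplicon = "16S") {
  ids <- readLines(path)
  spike_registry(ids[nzchar(ids)], amplicon = amplicon)
}

#' @rdname spike_registry
#' @param registry A `spike_registry` to write.
#' @export
write_spike_registry <- function(registry, path) {
  writeLines(registry$spike_ids, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Distance matrices
# ---------------------------------------------------------------------------

#' Construct, read or write a labelled distance matrix
#'
#' Pairwise sample dissimilarities are stored as a square labelled matrix;
#' validation enforces symmetry, a zero diagonal and non-negativity. The
#' text representation is a labelled square TSV that round-trips to the
#' printed precision.
#'
#' @param m Square numeric matrix with matching row/column names, or a
#'   `stats::dist` object.
#' @return A `dist_matrix` (a validated base matrix subclass).
#' @export
dist_matrix <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("Distance matrix must be square.")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  if (!identical(rownames(m), colnames(m)))
    abort("Distance matrix row and column labels differ.")
  if (any(m < 0)) abort("Distance matrix has a negative entry.")
  if (any(abs(diag(m)) > 1e-12))
    abort(sprintf("Nonzero diagonal at sample '%s'.",
                  rownames(m)[which(abs(diag(m)) > 1e-12)[1]]))
  if (max(abs(m - t(m))) > 1e-8) {
    ij <- which(abs(m - t(m)) == max(abs(m - t(m))), arr.ind = TRUE)[1, ]
    abort(sprintf("Asymmetric distance between '%s' and '%s'.",
                  rownames(m)[ij[1]], colnames(m)[ij[2]]))
  }
  diag(m) <- 0
  m <- (m + t(m)) / 2
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @rdname dist_matrix
#' @param dm A `dist_matrix`.
#' @param path File path.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dist_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  dist_matrix(as.matrix(df))
}

# ---------------------------------------------------------------------------
# Phylogenetic tree validation
# ---------------------------------------------------------------------------

#' Read and validate a rooted phylogeny for diversity analyses
#'
#' Trees come in as Newick (read with \pkg{ape}); validation requires a
#' rooted tree with unique tip labels and non-negative branch lengths, and
#' `check_tips()` confirms every queried ASV resolves to a tip — Faith's
#' phylogenetic diversity and weighted UniFrac are only defined when the
#' observed ASVs are on the tree.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_phylo_tree <- function(path) {
  validate_phylo_tree(ape::read.tree(path))
}

#' @rdname read_phylo_tree
#' @param tree An `ape::phylo` object.
#' @export
validate_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("Not a phylo tree.")
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  if (is.null(tree$edge.length)) abort("Tree lacks branch lengths.")
  if (any(tree$edge.length < 0)) abort("Negative branch length in tree.")
  if (anyDuplicated(tree$tip.label))
    abort(paste0("Duplicate tip label: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  tree
}

#' @rdname read_phylo_tree
#' @param asv_ids ASV identifiers that must resolve to tips.
#' @export
check_tips <- function(tree, asv_ids) {
  miss <- setdiff(asv_ids, tree$tip.label)
  if (length(miss) > 0)
    abort(paste0("ASVs absent from tree: ",
                 paste(head(miss, 5), collapse = ", ")))
  invisible(TRUE)
}

# internal: align an asv_table and metadata on shared samples, preserving
# table order
align_samples <- function(table, metadata) {
  keep <- intersect(rownames(table), metadata$sample_id)
  if (length(keep) == 0) abort("No samples shared by table and metadata.")
  md <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  list(table = table[keep, , drop = FALSE], metadata = md)
}
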