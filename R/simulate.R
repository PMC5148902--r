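#' Simulate a multi-group expression dataset with planted gene set signal
#'
#' Generates a genes x samples matrix for `m_groups` groups of `n_reps`
#' replicates each, on a log-like scale: per-gene baseline + Gaussian noise
#' with optional one-factor correlation blocks + an upward mean shift for the
#' member genes of each planted ("regulated") set in one designated group.
#'
#' The correlation model is a single shared latent factor per block: genes in
#' a block receive `sqrt(block_rho) * f_s + sqrt(1 - block_rho) * e_gs` noise
#' (times `noise_sd`), giving pairwise within-block correlation `block_rho`
#' identically in every group. Regulated sets are carved from the front of
#' the gene list, correlation blocks from the back; the two are kept
#' disjoint. Regulated set `k` is shifted up by `effect_size * noise_sd` in
#' group `(k - 1) %% m_groups + 1`.
#'
#' @param n_genes Number of genes.
#' @param m_groups Number of sample groups.
#' @param n_reps Replicates per group (constant across groups).
#' @param n_regulated_sets Number of planted differentially expressed sets.
#' @param set_size Genes per planted set.
#' @param effect_size Mean shift of regulated genes in their designated
#'   group, in units of `noise_sd`.
#' @param noise_sd Within-group noise standard deviation.
#' @param n_corr_blocks Number of gene-gene correlation blocks.
#' @param block_rho Pairwise correlation within a block, in `[0, 1)`.
#' @param block_size Genes per correlation block.
#' @param seed Integer seed; the simulation is a deterministic function of it.
#' @return An object of class `mgszm_sim`: list with `dataset`
#'   (an [expression_dataset()]), `regulated_sets` (a
#'   [gene_set_collection()] of the planted sets), `affected_group` (named
#'   character vector, set name -> shifted group) and `config`.
#' @examples
#' sim <- simulate_dataset(n_genes = 300, m_groups = 3, n_reps = 3,
#'                         n_regulated_sets = 2, set_size = 10, seed = 1)
#' sim$dataset
#' @export
simulate_dataset <- function(n_genes = 2000, m_groups = 6, n_reps = 3,
                             n_regulated_sets = 10, set_size = 20,
                             effect_size = 1.0, noise_sd = 1.0,
                             n_corr_blocks = 5, block_rho = 0.3,
                             block_size = 50, seed = 1) {
  stopifnot(n_genes >= 1, m_groups >= 1, n_reps >= 1,
            n_regulated_sets >= 0, set_size >= 1,
            noise_sd > 0, n_corr_blocks >= 0, block_size >= 1)
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)")
  n_reg <- n_regulated_sets * set_size
  n_blk <- n_corr_blocks * block_size
  if (n_reg > n_genes)
    stop("infeasible config: n_regulated_sets * set_size exceeds n_genes")
  if (n_reg + n_blk > n_genes)
    stop("infeasible config: regulated genes and correlation blocks ",
         "together exceed n_genes (they are kept disjoint)")

  groups_lab <- sprintf("G%d", seq_len(m_groups))
  groups <- rep(groups_lab, each = n_reps)
  sample_ids <- paste0(groups, "_R", rep(seq_len(n_reps), times = m_groups))
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  S <- m_groups * n_reps

  with_seed(seed, {
    baseline <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
    noise <- matrix(stats::rnorm(n_genes * S), n_genes, S)
    if (n_corr_blocks > 0 && block_rho > 0) {
      for (b in seq_len(n_corr_blocks)) {
        rows <- n_genes - n_blk + (b - 1L) * block_size + seq_len(block_size)
        f <- stats::rnorm(S)
        noise[rows, ] <- sqrt(block_rho) * matrix(f, block_size, S, byrow = TRUE) +
          sqrt(1 - block_rho) * noise[rows, ]
      }
    }
    values <- baseline + noise_sd * noise
    dimnames(values) <- list(gene_ids, sample_ids)

    affected <- character(0)
    sets <- list()
    if (n_regulated_sets > 0) {
      for (k in seq_len(n_regulated_sets)) {
        rows <- (k - 1L) * set_size + seq_len(set_size)
        g <- groups_lab[(k - 1L) %% m_groups + 1L]
        nm <- sprintf("SET_REG_%02d", k)
        sets[[nm]] <- gene_ids[rows]
        affected[nm] <- g
        if (effect_size != 0)
          values[rows, groups == g] <- values[rows, groups == g] +
            effect_size * noise_sd
      }
    }
    ds <- expression_dataset(values, stats::setNames(groups, sample_ids))
    reg <- if (length(sets))
      gene_set_collection(sets, sprintf("planted in %s", affected))
    else structure(list(sets = list(), descriptions = character(0)),
                   class = "gene_set_collection")
    structure(list(dataset = ds, regulated_sets = reg,
                   affected_group = affected,
                   config = list(n_genes = n_genes, m_groups = m_groups,
                                 n_reps = n_reps,
                                 n_regulated_sets = n_regulated_sets,
                                 set_size = set_size,
                                 effect_size = effect_size,
                                 noise_sd = noise_sd,
                                 n_corr_blocks = n_corr_blocks,
                                 block_rho = block_rho,
                                 block_size = block_size, seed = seed)),
              class = "mgszm_sim")
  })
}

#' @export
print.mgszm_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "mgszm_sim: %d genes, %d groups x %d reps; %d planted sets of %d genes (effect %.2f sd)\n",
    cfg$n_genes, cfg$m_groups, cfg$n_reps, cfg$n_regulated_sets,
    cfg$set_size, cfg$effect_size))
  invisible(x)
}

#' Write a simulation to the three standard files
#'
#' Writes `matrix.tsv` (expression), `groups.tsv` (sample-group map) and
#' `regulated_sets.gmt` (planted sets) into `dir`, so a simulated dataset
#' can be fed back through the file-based interface.
#'
#' @param sim An `mgszm_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mgszm_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "matrix.tsv")
  gp <- file.path(dir, "groups.tsv")
  sp <- file.path(dir, "regulated_sets.gmt")
  vals <- sim$dataset$values
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(sim$dataset$groups),
               group = unname(sim$dataset$groups)),
    gp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (length(sim$regulated_sets)) write_gmt(sim$regulated_sets, sp)
  invisible(c(matrix = mp, groups = gp, gmt = sp))
}

#' Generate benchmark gene sets with graded co-regulation
#'
#' Builds a collection of unregulated gene sets whose members are drawn
#' partly from the simulation's gene-gene correlation blocks and partly from
#' uncorrelated genes, with the co-regulated fraction spread evenly from 0
#' to 1 across sets. This emulates a curated collection: real gene sets
#' capture co-regulated genes to widely varying degrees, and that
#' heterogeneity is what spreads per-set null distributions apart. Purely
#' i.i.d. random sets of similar size have nearly identical nulls and make
#' between-set comparisons of null parameters degenerate.
#'
#' @param sim An `mgszm_sim` from [simulate_dataset()] with
#'   `n_corr_blocks >= 1`.
#' @param n_sets Number of sets to generate.
#' @param size_range Integer range of set sizes (sampled uniformly).
#' @param seed Integer seed.
#' @return A [gene_set_collection()] named `BM_001`, `BM_002`, ...
#' @export
benchmark_sets <- function(sim, n_sets = 100, size_range = c(10, 60),
                           seed = 1) {
  stopifnot(inherits(sim, "mgszm_sim"), n_sets >= 2)
  cfg <- sim$config
  if (cfg$n_corr_blocks < 1)
    stop("the simulation must contain at least one correlation block")
  genes <- rownames(sim$dataset$values)
  n_blk <- cfg$n_corr_blocks * cfg$block_size
  block_of <- function(b)
    genes[cfg$n_genes - n_blk + (b - 1L) * cfg$block_size +
            seq_len(cfg$block_size)]
  planted <- unique(unlist(sim$regulated_sets$sets))
  free <- setdiff(genes[seq_len(cfg$n_genes - n_blk)], planted)
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      M <- sample(seq(size_range[1], size_range[2]), 1L)
      f <- (i - 1) / (n_sets - 1)
      bg <- block_of(sample.int(cfg$n_corr_blocks, 1L))
      nb <- min(round(f * M), length(bg))
      c(sample_safe(bg, nb), sample_safe(free, M - nb))
    })
    names(sets) <- sprintf("BM_%03d", seq_len(n_sets))
    gene_set_collection(sets, sprintf("co-regulated fraction %.2f",
                                      (seq_len(n_sets) - 1) / (n_sets - 1)))
  })
}

#' Randomize the sample labels of a dataset (null data)
#'
#' Produces null gene expression data by randomly reassigning the existing
#' group labels to samples, as a permutation of the original label multiset.
#' The matrix itself is untouched; group sizes are preserved exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param seed Integer seed.
#' @return An [expression_dataset()] with shuffled labels.
#' @export
make_null_dataset <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(unique(dataset$groups)) < 2L)
    stop("need at least 2 groups to randomize labels")
  with_seed(seed, {
    new_labels <- sample(unname(dataset$groups))
    expression_dataset(dataset$values,
                       stats::setNames(new_labels, names(dataset$groups)))
  })
}

#' Dilute a gene set with random genes
#'
#' Replaces `x_percent`% of a specific gene set's members (rounded half away
#' from zero) with genes drawn from a disjoint pool, keeping the set size
#' fixed. Used to build benchmark sets of graded relevance: at `x = 90` a
#' size-10 set retains exactly one of its original genes.
#'
#' @param specific_genes Character vector (the original set).
#' @param x_percent Percentage to replace, typically on the grid
#'   0, 10, ..., 90.
#' @param gene_pool Character vector of replacement candidates; must be
#'   disjoint from `specific_genes` and large enough.
#' @param seed Integer seed.
#' @return Character vector of the same length as `specific_genes`.
#' @export
dilute_gene_set <- function(specific_genes, x_percent, gene_pool, seed = 1) {
  specific_genes <- unique(as.character(specific_genes))
  gene_pool <- unique(as.character(gene_pool))
  if (x_percent < 0 || x_percent > 100)
    stop("x_percent must lie in [0, 100]")
  if (length(intersect(specific_genes, gene_pool)))
    stop("gene_pool must be disjoint from specific_genes")
  k <- as.integer(round_half_up(x_percent / 100 * length(specific_genes)))
  if (k > length(gene_pool))
    stop(sprintf("gene pool too small: need %d replacement genes, have %d",
                 k, length(gene_pool)))
  if (k == 0L) return(specific_genes)
  with_seed(seed, {
    drop <- sample_safe(specific_genes, k)
    add <- sample_safe(gene_pool, k)
    c(setdiff(specific_genes, drop), add)
  })
}
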