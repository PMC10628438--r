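#' Simulate single-cell counts with planted co-expression modules
#'
#' Negative-binomial counts with a latent-factor module structure, the
#' standard noise model for scRNA-seq unique-molecule counts. Cells belong
#' to groups (emulating cell types) and, within each group, to blobs
#' (sub-populations giving the pseudo-cell stage a recoverable truth). Each
#' module m has a per-cell latent activity z_m drawn from Normal(mu_bm,
#' `factor_sd`), where mu_bm is a blob-specific shift; a gene of module m
#' has log-mean mu_g + loading * z_m, background genes carry no factor.
#' One gene per module is designated its driver TF and given loading 1.0;
#' the module's remaining genes form the driver's regulon. Counts are drawn
#' as NegativeBinomial(mean = exp(log-mean), dispersion = `nb_dispersion`)
#' (variance mu + dispersion * mu^2).
#'
#' @param n_groups number of cell groups (default 2).
#' @param cells_per_group cells per group (default 300).
#' @param blobs_per_group sub-populations per group (default 5).
#' @param n_genes total genes (default 1000).
#' @param n_modules planted modules (default 5).
#' @param module_size genes per module, driver included (default 60).
#' @param factor_sd within-blob latent activity spread (default 1.0).
#' @param loading module-gene loading on the latent factor (default 0.8;
#'   drivers always load at 1.0).
#' @param nb_dispersion negative-binomial dispersion (default 0.5).
#' @param base_mean_log_range range of per-gene baseline log-means
#'   (default c(0.5, 3.0), natural log).
#' @param seed integer seed.
#' @return list with `expr` (an [sc_expr] of counts with group/blob
#'   metadata) and `truth` (class `ground_truth`: `module_of`, `driver_tf`,
#'   `regulon`, `blob_of`, `motif_truth` placeholder filled by
#'   [simulate_motif_db]).
#' @export
simulate_counts <- function(n_groups = 2, cells_per_group = 300,
                            blobs_per_group = 5, n_genes = 1000,
                            n_modules = 5, module_size = 60,
                            factor_sd = 1.0, loading = 0.8,
                            nb_dispersion = 0.5,
                            base_mean_log_range = c(0.5, 3.0), seed = 1L) {
  if (n_modules * module_size > n_genes) {
    stop("n_modules * module_size exceeds n_genes", call. = FALSE)
  }
  if (any(c(n_groups, cells_per_group, blobs_per_group, n_genes) < 1)) {
    stop("inconsistent simulation sizes", call. = FALSE)
  }
  with_seed(seed, {
    n_cells <- n_groups * cells_per_group
    gene_ids <- character(n_genes)
    module_of <- stats::setNames(integer(n_genes), NULL)
    g <- 0L
    driver_tf <- character(n_modules)
    for (m in seq_len(n_modules)) {
      ids <- c(sprintf("TF%02d", m),
               sprintf("M%dG%03d", m, seq_len(module_size - 1L)))
      gene_ids[g + seq_len(module_size)] <- ids
      module_of[g + seq_len(module_size)] <- m
      driver_tf[m] <- ids[1]
      g <- g + module_size
    }
    if (g < n_genes) {
      gene_ids[(g + 1L):n_genes] <- sprintf("BG%04d", seq_len(n_genes - g))
    }
    names(module_of) <- gene_ids
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    group <- rep(sprintf("group%d", seq_len(n_groups)), each = cells_per_group)
    blob_local <- unlist(lapply(seq_len(n_groups), function(i)
      sort(rep_len(seq_len(blobs_per_group), cells_per_group))))
    blob <- paste0(group, ".b", blob_local)

    mu_g <- runif(n_genes, base_mean_log_range[1], base_mean_log_range[2])
    # blob-specific latent shifts per module
    blobs <- unique(blob)
    shift <- matrix(rnorm(length(blobs) * n_modules), length(blobs),
                    n_modules, dimnames = list(blobs, NULL))
    z <- matrix(0, n_cells, n_modules)
    for (m in seq_len(n_modules)) {
      z[, m] <- rnorm(n_cells, mean = shift[blob, m], sd = factor_sd)
    }
    logmean <- matrix(mu_g, n_cells, n_genes, byrow = TRUE)
    for (m in seq_len(n_modules)) {
      idx <- which(module_of == m)
      lam <- rep(loading, length(idx))
      lam[gene_ids[idx] == driver_tf[m]] <- 1.0
      logmean[, idx] <- logmean[, idx] + z[, m] %o% lam
    }
    counts <- matrix(rnbinom(n_cells * n_genes, mu = exp(logmean),
                             size = 1 / nb_dispersion),
                     n_cells, n_genes)
    md <- data.frame(cell_id = cell_ids, group = group, blob = blob,
                     stringsAsFactors = FALSE)
    expr <- sc_expr(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                    metadata = md, counts = TRUE)
    regulon <- lapply(stats::setNames(seq_len(n_modules), driver_tf),
                      function(m) setdiff(names(module_of)[module_of == m],
                                          driver_tf[m]))
    truth <- structure(list(
      module_of = module_of,
      driver_tf = stats::setNames(driver_tf, paste0("M", seq_len(n_modules))),
      regulon = regulon,
      blob_of = stats::setNames(blob, cell_ids),
      motif_truth = NULL), class = "ground_truth")
    list(expr = expr, truth = truth)
  })
}

#' Simulate a motif ranking database consistent with planted regulons
#'
#' For every planted driver TF one "true" motif is generated whose ranking
#' places a `signal_frac` fraction of the TF's regulon uniformly within the
#' top 5% of ranks (remaining genes get uniform random ranks); all other
#' motifs are independent uniform permutations. The annotation links each
#' true motif to its TF and additionally assigns 2 decoy motifs per TF, so
#' the enrichment filter has something to reject.
#'
#' @param truth a `ground_truth` from [simulate_counts].
#' @param n_motifs total motifs (default 50).
#' @param signal_frac fraction of the regulon placed in the top region
#'   (default 0.9).
#' @param seed integer seed.
#' @return a [motif_db]; also records motif->TF truth in its
#'   `motif_truth` attribute.
#' @export
simulate_motif_db <- function(truth, n_motifs = 50, signal_frac = 0.9,
                              seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), length(truth$regulon) >= 1L)
  genes <- names(truth$module_of)
  G <- length(genes)
  tfs <- names(truth$regulon)
  n_true <- length(tfs)
  if (n_motifs < n_true + 2L * n_true) {
    stop("n_motifs too small for true motifs plus 2 decoys per TF",
         call. = FALSE)
  }
  top_n <- ceiling(0.05 * G)
  with_seed(seed, {
    ranks <- matrix(0L, n_motifs, G)
    motif_ids <- c(sprintf("motif_true_%s", tfs),
                   sprintf("motif_decoy_%03d", seq_len(n_motifs - n_true)))
    rownames(ranks) <- motif_ids
    colnames(ranks) <- genes
    for (i in seq_len(n_true)) {
      reg <- truth$regulon[[tfs[i]]]
      n_sig <- min(round(signal_frac * length(reg)), top_n)
      sig <- if (n_sig > 0) sample(reg, n_sig) else character()
      r <- integer(G)
      top_ranks <- sample(seq_len(top_n), length(sig))
      r[match(sig, genes)] <- top_ranks
      rest <- setdiff(seq_len(G), top_ranks)
      r[r == 0L] <- sample(rest)
      ranks[i, ] <- r
    }
    for (i in (n_true + 1L):n_motifs) {
      ranks[i, ] <- sample.int(G)
    }
    decoy_pool <- motif_ids[(n_true + 1L):n_motifs]
    ann <- data.frame(
      motif_id = c(motif_ids[seq_len(n_true)],
                   decoy_pool[seq_len(2L * n_true)]),
      tf = c(tfs, rep(tfs, each = 2L)),
      stringsAsFactors = FALSE)
    db <- motif_db(ranks, ann)
    attr(db, "motif_truth") <- stats::setNames(tfs, motif_ids[seq_len(n_true)])
    db
  })
}

#' Simulate a drug-target snapshot table
#'
#' Each drug targets 1 to 3 uniformly sampled genes; deterministic under
#' seed.
#'
#' @param genes gene universe to sample targets from.
#' @param n_drugs number of drugs (default 30; must be >= 1).
#' @param max_targets_per_drug upper bound on targets per drug (default 3).
#' @param seed integer seed.
#' @return a [drug_table].
#' @export
simulate_drug_table <- function(genes, n_drugs = 30,
                                max_targets_per_drug = 3, seed = 1L) {
  if (n_drugs < 1L) stop("n_drugs must be >= 1", call. = FALSE)
  with_seed(seed, {
    recs <- lapply(seq_len(n_drugs), function(d) {
      k <- sample.int(max_targets_per_drug, 1L)
      data.frame(drug_id = sprintf("D%03d", d),
                 drug_name = sprintf("drug_%03d", d),
                 gene_symbol = sample(genes, min(k, length(genes))),
                 action = "", source = "synthetic",
                 stringsAsFactors = FALSE)
    })
    drug_table(do.call(rbind, recs), provenance = "synthetic snapshot")
  })
}

#' Write the default synthetic scenario to disk as fixture files
#'
#' Generates counts, metadata, TF list, motif ranking database and drug
#' table under `dir` in the package's standard file formats, so every
#' pipeline stage can be exercised from files alone.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param ... overrides passed to [simulate_counts].
#' @return invisibly, the `list(expr, truth, db, drugs)` that was written.
#' @export
write_synthetic_scenario <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(seed = seed, ...)
  db <- simulate_motif_db(sim$truth, seed = seed + 1L)
  drugs <- simulate_drug_table(names(sim$truth$module_of), seed = seed + 2L)
  write_expression(sim$expr, file.path(dir, "counts.tsv"))
  write_tsv(sim$expr$metadata, file.path(dir, "metadata.tsv"))
  writeLines(unname(sim$truth$driver_tf), file.path(dir, "tfs.txt"))
  write_motif_db(db, file.path(dir, "motif_ranks.tsv"),
                 file.path(dir, "motif2tf.tsv"))
  write_tsv(as.data.frame(drugs), file.path(dir, "drugs.tsv"))
  invisible(list(expr = sim$expr, truth = sim$truth, db = db, drugs = drugs))
}
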