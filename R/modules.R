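#' Module eigengenes and explained variance
#'
#' The eigengene of a module is the first principal-component score vector of
#' the module's z-scored expression (unit-normalized over samples), the
#' standard one-vector summary profile of the module. Its sign is oriented so
#' that the mean correlation with the member genes is non-negative.
#' `var_explained` is the leading eigenvalue divided by the total variance.
#' The unassigned (grey, label 0) pool gets no eigengene. A single-gene
#' module's eigengene is that gene's z-score, unit-normalized (reported via
#' message).
#'
#' @param expr an [sc_expr] object or samples x genes matrix.
#' @param labels integer module labels named by gene (0 = unassigned).
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `ME<id>`) and `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, labels) {
  X <- if (inherits(expr, "sc_expr")) expr$values else as.matrix(expr)
  labels <- labels[colnames(X)]
  mods <- sort(unique(labels[labels != 0]))
  ME <- matrix(NA_real_, nrow(X), length(mods),
               dimnames = list(rownames(X), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    sub <- X[, genes, drop = FALSE]
    Z <- scale(sub)
    Z[, !is.finite(colSums(Z))] <- 0
    if (length(genes) == 1L) {
      message(sprintf("module %d has a single gene; eigengene is its z-score",
                      mods[i]))
      e <- Z[, 1]
      nrm <- sqrt(sum(e^2))
      if (nrm > 0) e <- e / nrm
      ME[, i] <- e
      ve[i] <- 1
      next
    }
    sv <- svd(Z, nu = 1, nv = 0)
    e <- sv$u[, 1]
    tot <- sum(sv$d^2)
    ve[i] <- if (tot > 0) sv$d[1]^2 / tot else 0
    mc <- suppressWarnings(cor(e, sub))
    if (mean(mc, na.rm = TRUE) < 0) e <- -e
    ME[, i] <- e
  }
  list(eigengenes = ME, var_explained = ve)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM with
#' a static branch cut: clusters are taken below `cut_height` (default
#' 0.995 x the tallest merge), clusters smaller than `min_module_size` go to
#' the unassigned pool (label 0), and modules whose eigengenes correlate at
#' or above `1 - merge_cut` are merged iteratively, closest pair first.
#' Surviving modules are renumbered 1..M by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity].
#' @param expr expression (samples x genes, or [sc_expr]) used for
#'   eigengene-based merging.
#' @param min_module_size smallest allowed module (default 30).
#' @param cut_height static cut height; default `0.995 * max(tree height)`.
#' @param merge_cut eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. merge at correlation >= 0.75).
#' @return list of class `module_set`: `labels` (named integer vector),
#'   `eigengenes`, `var_explained`, `tree` (hclust), `cut_height`,
#'   `n_merged`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30,
                           cut_height = NULL, merge_cut = 0.25) {
  X <- if (inherits(expr, "sc_expr")) expr$values else as.matrix(expr)
  stopifnot(ncol(X) == ncol(tom))
  genes <- colnames(tom) %||% colnames(X)
  tree <- hclust(as.dist(1 - tom), method = "average")
  # guard against floating-point non-monotonicity under tied dissimilarities
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  if (is.null(cut_height)) cut_height <- 0.995 * max(tree$height)
  raw <- cutree(tree, h = cut_height)
  names(raw) <- genes
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- ifelse(raw %in% keep, raw, 0L)
  names(labels) <- genes
  if (all(labels == 0L)) {
    warning("all genes unassigned (grey); no module passed the size cut",
            call. = FALSE)
    return(structure(list(labels = labels, eigengenes = NULL,
                          var_explained = NULL, tree = tree,
                          cut_height = cut_height, n_merged = 0L),
                     class = "module_set"))
  }
  labels <- renumber_by_size(labels)

  # iterative closest-pair eigengene merge
  n_merged <- 0L
  repeat {
    eg <- module_eigengenes(X, labels)
    ids <- as.integer(sub("^ME", "", colnames(eg$eigengenes)))
    if (length(ids) < 2L) break
    C <- cor(eg$eigengenes)
    diag(C) <- -Inf
    if (max(C) < 1 - merge_cut) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    a <- ids[ij[1]]; b <- ids[ij[2]]
    labels[labels == b] <- a
    labels <- renumber_by_size(labels)
    n_merged <- n_merged + 1L
  }
  eg <- module_eigengenes(X, labels)
  structure(list(labels = labels, eigengenes = eg$eigengenes,
                 var_explained = eg$var_explained, tree = tree,
                 cut_height = cut_height, n_merged = n_merged),
            class = "module_set")
}

renumber_by_size <- function(labels) {
  ids <- unique(labels[labels != 0])
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  first_gene <- vapply(ids, function(i) names(labels)[labels == i][1],
                       character(1))
  ord <- ids[order(-sizes, first_gene)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  new
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels != 0]))
  cat(sprintf("module_set: %d modules over %d genes (%d unassigned)\n",
              n_mod, length(x$labels), sum(x$labels == 0)))
  invisible(x)
}

#' Module-trait correlation
#'
#' Correlates each module eigengene with each trait over the representative
#' cells (Spearman by default). Categorical traits are expanded to one-hot
#' indicator vectors (`trait.level`); numeric traits are used as-is.
#' P-values are asymptotic and Benjamini-Hochberg adjusted across the whole
#' module x trait matrix. A constant trait vector has undefined correlation
#' and is reported as 0 with `constant = TRUE`.
#'
#' @param eigengenes samples x modules matrix (from [detect_modules]).
#' @param metadata per-sample data.frame; a `cell_id` column is ignored.
#' @param method correlation method (default `"spearman"`).
#' @param traits optional subset of metadata columns to use.
#' @return data.frame with columns module, trait, rho, p, p_adj, constant.
#' @export
module_trait_correlation <- function(eigengenes, metadata,
                                     method = "spearman", traits = NULL) {
  md <- as.data.frame(metadata)
  md <- md[, setdiff(names(md), "cell_id"), drop = FALSE]
  if (!is.null(traits)) md <- md[, traits, drop = FALSE]
  tvec <- list()
  for (nm in names(md)) {
    v <- md[[nm]]
    if (is.numeric(v)) {
      tvec[[nm]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      for (lev in unique(v)) {
        tvec[[paste(nm, lev, sep = ".")]] <- as.numeric(v == lev)
      }
    }
  }
  out <- expand.grid(module = colnames(eigengenes), trait = names(tvec),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_; out$constant <- FALSE
  for (i in seq_len(nrow(out))) {
    e <- eigengenes[, out$module[i]]
    t <- tvec[[out$trait[i]]]
    if (var(t) == 0) {
      out$rho[i] <- 0; out$p[i] <- 1; out$constant[i] <- TRUE
      next
    }
    ct <- suppressWarnings(cor.test(e, t, method = method, exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  if (any(out$constant)) {
    warning(sprintf("%d constant trait vector(s); correlation reported as 0",
                    sum(vapply(split(out$constant, out$trait), any, logical(1)))),
            call. = FALSE)
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Intramodular connectivity
#'
#' kIM of gene i is the sum of adjacencies to genes of its own module
#' (excluding self). Unassigned genes get kIM = 0.
#'
#' @param adj adjacency matrix.
#' @param labels named module labels.
#' @return named numeric vector.
#' @export
intramodular_connectivity <- function(adj, labels) {
  genes <- colnames(adj)
  labels <- labels[genes]
  kIM <- stats::setNames(numeric(length(genes)), genes)
  for (m in unique(labels[labels != 0])) {
    idx <- which(labels == m)
    sub <- adj[idx, idx, drop = FALSE]
    diag(sub) <- 0
    kIM[idx] <- rowSums(sub)
  }
  kIM
}

#' Module membership (kME)
#'
#' kME of gene i is its correlation (same method as the network) with its own
#' module's eigengene. Unassigned genes get 0.
#'
#' @param expr samples x genes matrix or [sc_expr].
#' @param eigengenes samples x modules eigengene matrix.
#' @param labels named module labels.
#' @param method correlation method used for the network (default bicor).
#' @return named numeric vector in \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes, labels,
                              method = c("bicor", "pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(expr, "sc_expr")) expr$values else as.matrix(expr)
  labels <- labels[colnames(X)]
  kME <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    m <- labels[j]
    if (m == 0 || !paste0("ME", m) %in% colnames(eigengenes)) next
    e <- eigengenes[, paste0("ME", m)]
    kME[j] <- switch(method,
      bicor = suppressMessages(bicor(X[, j], e)),
      pearson = cor(X[, j], e),
      spearman = cor(X[, j], e, method = "spearman"))
    if (!is.finite(kME[j])) kME[j] <- 0
  }
  kME
}

#' Hub genes of one module
#'
#' Hubs are the intersection of the top `top_frac` (default top 10%) genes
#' by intramodular connectivity (kIM) and the top `top_frac` by module
#' membership (kME); ties broken lexicographically by gene symbol. With m
#' module genes, each top list has ceiling(top_frac * m) entries.
#'
#' @param module_genes gene symbols of the module.
#' @param kIM,kME named score vectors covering the module genes.
#' @param top_frac fraction defining the two top lists (default 0.10).
#' @return character vector of hub genes (possibly empty).
#' @export
detect_hubs <- function(module_genes, kIM, kME, top_frac = 0.10) {
  m <- length(module_genes)
  if (m < 2L) {
    warning("module has fewer than 2 genes; no hubs", call. = FALSE)
    return(character())
  }
  t <- ceiling(top_frac * m)
  top_by <- function(score) {
    s <- score[module_genes]
    module_genes[order(-s, module_genes)][seq_len(t)]
  }
  sort(intersect(top_by(kIM), top_by(kME)))
}

#' Extract a correlation-thresholded sub-network of a module
#'
#' Keeps within-module edges whose correlation meets the threshold (absolute
#' value for unsigned networks, raw value otherwise); returns the genes
#' incident to at least one kept edge together with the edge list.
#'
#' @param cor correlation matrix.
#' @param module_genes genes of the module.
#' @param threshold correlation threshold in \[0, 1\].
#' @param signed if FALSE, |cor| is compared to the threshold.
#' @return list with `genes` and `edges` (data.frame gene1, gene2, cor).
#' @export
extract_submodule <- function(cor, module_genes, threshold, signed = TRUE) {
  stopifnot(threshold >= 0)
  sub <- cor[module_genes, module_genes, drop = FALSE]
  val <- if (signed) sub else abs(sub)
  m <- length(module_genes)
  keep <- which(upper.tri(val) & val >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene1 = module_genes[keep[, 1]],
                      gene2 = module_genes[keep[, 2]],
                      cor = sub[keep], stringsAsFactors = FALSE)
  list(genes = sort(unique(c(edges$gene1, edges$gene2))), edges = edges)
}

#' Fit a weighted gene co-expression network
#'
#' End-to-end module inference on (representative-cell) expression:
#' correlation, soft-threshold selection, adjacency, topological overlap,
#' module detection with eigengene merging, intramodular connectivity and
#' module membership, hub calling, scale-free fit, and (when metadata is
#' present) module-trait correlation.
#'
#' @param expr an [sc_expr] object (samples = representative cells).
#' @param method gene-gene correlation method (default `"bicor"`, robust to
#'   outliers; trait correlation always uses `trait_method`).
#' @param network_type adjacency variant (default `"signed"`).
#' @param power soft power; `NULL` (default) picks it via
#'   [pick_soft_threshold].
#' @param powers,r2_cut candidate powers and fit cut for automatic selection.
#' @param min_module_size,cut_height,merge_cut module detection controls,
#'   see [detect_modules].
#' @param top_frac hub fraction, see [detect_hubs].
#' @param traits metadata columns to correlate modules with (default: all
#'   except cell_id and size).
#' @param trait_method correlation for module-trait association (default
#'   Spearman).
#' @return object of class `gcn_fit` with elements `cor`, `adjacency`,
#'   `tom`, `power`, `soft_threshold`, `modules`, `kIM`, `kME`, `hubs`,
#'   `scale_free`, `trait_cor`, `params`.
#' @export
fit_gcn <- function(expr, method = "bicor", network_type = "signed",
                    power = NULL, powers = 1:20, r2_cut = 0.85,
                    min_module_size = 30, cut_height = NULL,
                    merge_cut = 0.25, top_frac = 0.10,
                    traits = NULL, trait_method = "spearman") {
  stopifnot(inherits(expr, "sc_expr"))
  C <- correlation_matrix(expr, method = method)
  sft <- NULL
  if (is.null(power)) {
    sft <- pick_soft_threshold(C, network_type, powers, r2_cut,
                               n_samples = nrow(expr$values))
    power <- sft$power
  }
  A <- adjacency_matrix(C, network_type, power)
  TOM <- tom_similarity(A)
  mods <- detect_modules(TOM, expr, min_module_size = min_module_size,
                         cut_height = cut_height, merge_cut = merge_cut)
  kIM <- intramodular_connectivity(A, mods$labels)
  kME <- if (is.null(mods$eigengenes)) {
    stats::setNames(numeric(length(mods$labels)), names(mods$labels))
  } else {
    module_membership(expr, mods$eigengenes, mods$labels, method = method)
  }
  mod_ids <- sort(unique(mods$labels[mods$labels != 0]))
  hubs <- if (length(mod_ids) == 0L) list() else {
    lapply(stats::setNames(mod_ids, paste0("M", mod_ids)), function(m) {
      detect_hubs(names(mods$labels)[mods$labels == m], kIM, kME, top_frac)
    })
  }
  sf <- tryCatch(scale_free_fit(A), error = function(e) NULL)
  trait_cor <- NULL
  if (!is.null(expr$metadata)) {
    tcols <- traits %||% setdiff(names(expr$metadata), c("cell_id", "size"))
    if (length(tcols) > 0L && !is.null(mods$eigengenes)) {
      trait_cor <- module_trait_correlation(mods$eigengenes, expr$metadata,
                                            method = trait_method,
                                            traits = tcols)
    }
  }
  structure(list(cor = C, adjacency = A, tom = TOM, power = power,
                 soft_threshold = sft, modules = mods, kIM = kIM, kME = kME,
                 hubs = hubs, scale_free = sf, trait_cor = trait_cor,
                 params = list(method = method, network_type = network_type,
                               min_module_size = min_module_size,
                               merge_cut = merge_cut, top_frac = top_frac)),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  n_mod <- length(unique(x$modules$labels[x$modules$labels != 0]))
  cat(sprintf("gcn_fit: %s/%s network, power %d; %d modules, %d genes unassigned\n",
              x$params$method, x$params$network_type, x$power,
              n_mod, sum(x$modules$labels == 0)))
  if (!is.null(x$scale_free)) {
    cat(sprintf("scale-free fit index: %.3f\n", x$scale_free$r2))
  }
  invisible(x)
}

#' @export
summary.gcn_fit <- function(object, ...) {
  labels <- object$modules$labels
  ids <- sort(unique(labels[labels != 0]))
  df <- data.frame(
    module = paste0("M", ids),
    size = vapply(ids, function(m) sum(labels == m), integer(1)),
    var_explained = unname(object$modules$var_explained[paste0("ME", ids)]),
    n_hubs = vapply(paste0("M", ids), function(m)
      length(object$hubs[[m]]), integer(1)))
  df
}

#' @export
plot.gcn_fit <- function(x, ...) {
  plot(x$modules$tree, labels = FALSE, hang = -1,
       main = "Gene dendrogram (1 - TOM)", xlab = "", sub = "", ...)
  graphics::abline(h = x$modules$cut_height, col = "red", lty = 2)
  invisible(x)
}

#' Export a fitted co-expression network's tables
#'
#' Writes the standard result tables: per-gene module assignment with kIM,
#' kME and hub flag; eigengenes; module-trait correlations.
#'
#' @param fit a `gcn_fit` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_gcn <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- fit$modules$labels
  hubs <- unlist(fit$hubs, use.names = FALSE)
  genes_df <- data.frame(
    gene = names(labels), module = unname(labels),
    kIM = unname(fit$kIM[names(labels)]), kME = unname(fit$kME[names(labels)]),
    is_hub = names(labels) %in% hubs, stringsAsFactors = FALSE)
  p1 <- file.path(dir, "modules.tsv")
  write_edge_table(genes_df, p1)
  paths <- p1
  if (!is.null(fit$modules$eigengenes)) {
    eg <- data.frame(cell_id = rownames(fit$modules$eigengenes),
                     fit$modules$eigengenes, check.names = FALSE)
    p2 <- file.path(dir, "eigengenes.tsv"); write_tsv(eg, p2)
    paths <- c(paths, p2)
  }
  if (!is.null(fit$trait_cor)) {
    p3 <- file.path(dir, "module_trait.tsv")
    write_edge_table(fit$trait_cor, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
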