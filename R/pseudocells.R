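#' Build representative cells by within-group sub-clustering
#'
#' Cells are split by a categorical metadata column (typically cell type).
#' Within each group, cells are partitioned into exactly `n_subclusters`
#' sub-clusters by k-means (k-means++ initialization, fixed seed) on the top
#' principal components of the group's z-scored expression, and each
#' sub-cluster is collapsed to one representative cell by the per-gene
#' arithmetic mean of its member cells. Averaging happens on whatever scale
#' the input is in; log-normalize first (see [normalize_counts]) unless raw
#' averaging is intended.
#'
#' Groups with fewer than `n_subclusters` cells are dropped with a warning so
#' that every retained group contributes the same number of representative
#' cells.
#'
#' @param expr an [sc_expr] object with metadata attached.
#' @param group_column name of the categorical metadata column defining groups.
#' @param n_subclusters number of sub-clusters per group (N >= 1).
#' @param seed integer seed controlling the clustering.
#' @param embedding_dims number of principal components for the embedding
#'   (default 50, capped at group size - 1 and gene count).
#' @return object of class `pseudocells`: list with `expr` (representative
#'   cells as [sc_expr], metadata inheriting the group label and recording
#'   member counts), `assignment` (data.frame cell_id, group, subcluster),
#'   `sizes`, and `n_subclusters`.
#' @export
make_representative_cells <- function(expr, group_column, n_subclusters,
                                      seed = 1L, embedding_dims = 50L) {
  stopifnot(inherits(expr, "sc_expr"))
  if (is.null(expr$metadata) || !group_column %in% names(expr$metadata)) {
    stop(sprintf("metadata column '%s' not found", group_column), call. = FALSE)
  }
  n_subclusters <- as.integer(n_subclusters)
  if (is.na(n_subclusters) || n_subclusters < 1L) {
    stop("n_subclusters must be >= 1", call. = FALSE)
  }
  groups <- as.character(expr$metadata[[group_column]])
  glev <- unique(groups)
  small <- glev[table(factor(groups, levels = glev)) < n_subclusters]
  if (length(small) > 0L) {
    warning(sprintf("dropping %d group(s) with fewer than %d cells: %s",
                    length(small), n_subclusters,
                    paste(small, collapse = ", ")), call. = FALSE)
    glev <- setdiff(glev, small)
  }
  if (length(glev) == 0L) stop("no group has enough cells", call. = FALSE)

  rep_values <- list(); rep_ids <- character(); rep_group <- character()
  rep_size <- integer()
  assignment <- data.frame(cell_id = character(), group = character(),
                           subcluster = integer(), stringsAsFactors = FALSE)
  for (gi in seq_along(glev)) {
    g <- glev[gi]
    idx <- which(groups == g)
    vals <- expr$values[idx, , drop = FALSE]
    cl <- subcluster_group(vals, n_subclusters, seed + gi,
                           embedding_dims, group = g)
    for (k in seq_len(n_subclusters)) {
      members <- idx[cl == k]
      rep_values[[length(rep_values) + 1L]] <-
        colMeans(expr$values[members, , drop = FALSE])
      rep_ids <- c(rep_ids, sprintf("%s.rc%02d", g, k))
      rep_group <- c(rep_group, g)
      rep_size <- c(rep_size, length(members))
    }
    assignment <- rbind(assignment, data.frame(
      cell_id = expr$cell_ids[idx], group = g, subcluster = cl,
      stringsAsFactors = FALSE))
  }
  vals <- do.call(rbind, rep_values)
  md <- data.frame(cell_id = rep_ids, group = rep_group, size = rep_size,
                   stringsAsFactors = FALSE)
  names(md)[2] <- group_column
  out_expr <- sc_expr(vals, gene_ids = expr$gene_ids, cell_ids = rep_ids,
                      metadata = md)
  structure(list(expr = out_expr, assignment = assignment,
                 sizes = stats::setNames(rep_size, rep_ids),
                 n_subclusters = n_subclusters),
            class = "pseudocells")
}

# k-means (k-means++ seeding) on a PCA embedding of z-scored expression.
# Retries with a perturbed seed up to 5 times if any cluster comes back empty.
subcluster_group <- function(vals, k, seed, embedding_dims, group = "?") {
  n <- nrow(vals)
  if (k == 1L) return(rep(1L, n))
  if (k == n) return(seq_len(n))
  z <- scale(vals)
  z[, !is.finite(colSums(z))] <- 0
  attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
  d <- min(embedding_dims, n - 1L, ncol(z))
  emb <- with_seed(seed, {
    pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = d)
    pc$x
  })
  for (attempt in 0:4) {
    res <- with_seed(seed + 1000L * attempt, {
      centers <- kmeanspp_centers(emb, k)
      tryCatch(kmeans(emb, centers = centers, iter.max = 100L),
               error = function(e) NULL)
    })
    if (!is.null(res) && all(tabulate(res$cluster, k) > 0L)) {
      return(res$cluster)
    }
  }
  stop(sprintf("group '%s': k-means produced an empty sub-cluster in 5 attempts",
               group), call. = FALSE)
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  ctr_idx <- integer(k)
  ctr_idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[ctr_idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ctr_idx[j] <- sample.int(n, 1L, prob = p)
    nd <- rowSums((x - matrix(x[ctr_idx[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  # nudge duplicates apart so stats::kmeans accepts the centers
  ctrs <- x[ctr_idx, , drop = FALSE]
  if (anyDuplicated(ctrs)) {
    ctrs <- ctrs + matrix(rnorm(length(ctrs), sd = 1e-8), nrow(ctrs))
  }
  ctrs
}

#' @export
print.pseudocells <- function(x, ...) {
  cat(sprintf("pseudocells: %d representative cells (%d per group) from %d cells\n",
              length(x$expr$cell_ids), x$n_subclusters, nrow(x$assignment)))
  invisible(x)
}
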