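#' Transcription factors present in a module
#'
#' Intersects a module's genes with a known-TF symbol list, preserving the
#' module's gene order.
#'
#' @param module_genes gene symbols of the module.
#' @param tf_list known TF symbols (see [read_tf_list]).
#' @return character vector of TFs.
#' @export
scan_tfs <- function(module_genes, tf_list) {
  tfs <- module_genes[module_genes %in% tf_list]
  if (length(tfs) == 0L) {
    stop("module contains no known TFs", call. = FALSE)
  }
  tfs
}

#' Candidate regulatory edges by gradient-boosted regression
#'
#' For each target gene, a stochastic gradient-boosted ensemble of shallow
#' regression trees predicts the target's expression from the TF expressions
#' (the target itself is excluded from its own predictors). Per round a
#' `subsample` fraction of samples and a sqrt-sized random subset of TFs are
#' used; boosting stops early once the mean out-of-bag squared-error
#' improvement over the last `early_stop_window` rounds drops to zero or
#' below. The importance of a TF for a target is the total impurity (sum of
#' squares) reduction over all its splits in the ensemble. One candidate
#' edge is emitted per (tf, target) pair with positive importance; edges are
#' sorted by decreasing importance and optionally capped per TF.
#'
#' @param expr [sc_expr] or samples x genes matrix containing TFs and
#'   targets.
#' @param tfs regulator symbols.
#' @param targets target gene symbols (typically the module's genes).
#' @param n_trees_max maximum boosting rounds per target (default 500).
#' @param learning_rate shrinkage (default 0.01).
#' @param subsample row-subsampling fraction per round (default 0.9).
#' @param early_stop_window rounds over which out-of-bag improvement is
#'   averaged for early stopping (default 25).
#' @param max_depth tree depth (default 3).
#' @param top_per_tf keep at most this many edges per TF before motif
#'   filtering (default 50; `Inf` disables the cap).
#' @param seed integer seed; each target uses a seed derived from it.
#' @return data.frame of class `candidate_edges` with columns tf, target,
#'   importance, sorted by decreasing importance.
#' @export
infer_candidates <- function(expr, tfs, targets, n_trees_max = 500,
                             learning_rate = 0.01, subsample = 0.9,
                             early_stop_window = 25, max_depth = 3,
                             top_per_tf = 50, seed = 1L) {
  X <- if (inherits(expr, "sc_expr")) expr$values else as.matrix(expr)
  if (nrow(X) < 10L) {
    stop("regulatory inference requires at least 10 samples", call. = FALSE)
  }
  missing <- setdiff(c(tfs, targets), colnames(X))
  if (length(missing) > 0L) {
    stop(sprintf("genes absent from expression: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    preds <- setdiff(tfs, tg)
    if (length(preds) == 0L) next
    y <- X[, tg]
    if (var(y) == 0) {
      warning(sprintf("target %s is constant; skipped", tg), call. = FALSE)
      next
    }
    imp <- with_seed(seed + 7919L * ti, boost_importance(
      X[, preds, drop = FALSE], y, n_trees_max, learning_rate, subsample,
      early_stop_window, max_depth))
    pos <- imp[imp > 0]
    if (length(pos) > 0L) {
      out[[tg]] <- data.frame(tf = names(pos), target = tg,
                              importance = unname(pos),
                              stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(), target = character(), importance = numeric())
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) {
    warning("no candidate edges (no informative TF splits)", call. = FALSE)
  }
  edges <- edges[order(-edges$importance, edges$tf, edges$target), ,
                 drop = FALSE]
  if (is.finite(top_per_tf) && nrow(edges) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$tf), function(i)
      head(i, top_per_tf)), use.names = FALSE)
    edges <- edges[sort(keep), , drop = FALSE]
  }
  rownames(edges) <- NULL
  class(edges) <- c("candidate_edges", "data.frame")
  edges
}

# One boosted ensemble: returns per-predictor total SSE gain.
boost_importance <- function(X, y, n_trees_max, learning_rate, subsample,
                             early_stop_window, max_depth) {
  n <- nrow(X); p <- ncol(X)
  n_feat <- max(1L, round(sqrt(p)))
  n_sub <- max(2L, floor(subsample * n))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = max(5L, floor(n_sub / 20)),
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  F <- rep(mean(y), n)
  imp <- stats::setNames(numeric(p), colnames(X))
  oob_imp <- numeric(n_trees_max)
  for (m in seq_len(n_trees_max)) {
    idx <- sample.int(n, n_sub)
    oob <- setdiff(seq_len(n), idx)
    feats <- sort(sample.int(p, n_feat))
    r <- y - F
    df <- as.data.frame(X[idx, feats, drop = FALSE])
    df$.r <- r[idx]
    fit <- rpart::rpart(.r ~ ., data = df, method = "anova", control = ctrl)
    g <- rpart_gains(fit)
    if (length(g) > 0L) imp[names(g)] <- imp[names(g)] + g
    step <- learning_rate *
      predict(fit, as.data.frame(X[, feats, drop = FALSE]))
    if (length(oob) > 0L) {
      oob_imp[m] <- mean(r[oob]^2) - mean((r[oob] - step[oob])^2)
    }
    F <- F + step
    if (m >= early_stop_window &&
        mean(oob_imp[(m - early_stop_window + 1L):m]) <= 0) break
  }
  imp
}

# SSE reduction per split variable from a fitted rpart tree.
rpart_gains <- function(fit) {
  fr <- fit$frame
  internal <- which(fr$var != "<leaf>")
  if (length(internal) == 0L) return(numeric())
  node <- as.integer(rownames(fr))
  gains <- numeric(length(internal))
  for (i in seq_along(internal)) {
    k <- node[internal[i]]
    kids <- match(c(2L * k, 2L * k + 1L), node)
    gains[i] <- fr$dev[internal[i]] - sum(fr$dev[kids])
  }
  tapply(gains, as.character(fr$var[internal]), sum)
}

#' Cis-regulatory motif enrichment of candidate target sets
#'
#' For each TF's candidate target set S and each motif in the ranking
#' database, computes the recovery AUC over the top `T = ceiling(
#' rank_threshold_frac * G)` ranks: with c(r) the number of members of S
#' ranked at or better than r, AUC = sum_{r=1..T} c(r) / (T * |S|). The
#' normalized enrichment score (NES) of a motif is its AUC standardized
#' against the mean and standard deviation of all motifs' AUCs for the same
#' set. Motifs annotated to the TF with NES at or above `nes_cut` are called
#' enriched; the leading edge of a motif is the subset of S within the top-T
#' region of its ranking.
#'
#' @param tf_targets named list mapping each TF to its candidate target
#'   symbols (targets absent from the database are dropped with a warning).
#' @param db a [motif_db].
#' @param rank_threshold_frac top fraction of the ranking considered
#'   (default 0.05).
#' @param nes_cut NES threshold for enrichment (default 3.0).
#' @return object of class `motif_enrichment`: list with `table`
#'   (data.frame tf, motif_id, auc, nes, annotated, enriched) and
#'   `leading_edge` (nested list \[tf\]\[motif_id\]).
#' @export
motif_enrichment <- function(tf_targets, db, rank_threshold_frac = 0.05,
                             nes_cut = 3.0) {
  stopifnot(inherits(db, "motif_db"))
  G <- length(db$gene_ids)
  T_ <- ceiling(rank_threshold_frac * G)
  rows <- list(); le <- list()
  for (tf in names(tf_targets)) {
    S <- unique(tf_targets[[tf]])
    dropped <- setdiff(S, db$gene_ids)
    if (length(dropped) > 0L) {
      warning(sprintf("%s: %d target(s) absent from motif db dropped",
                      tf, length(dropped)), call. = FALSE)
      S <- setdiff(S, dropped)
    }
    if (length(S) == 0L) next
    rk <- db$ranks[, S, drop = FALSE]
    inT <- rk <= T_
    auc <- rowSums(ifelse(inT, T_ - rk + 1L, 0L)) / (T_ * length(S))
    mu <- mean(auc); sdev <- sd(auc)
    if (is.na(sdev) || sdev == 0) {
      warning(sprintf("%s: zero spread of motif AUCs; NES undefined", tf),
              call. = FALSE)
      nes <- rep(NA_real_, length(auc))
    } else {
      nes <- (auc - mu) / sdev
    }
    annotated <- db$motif_ids %in%
      db$motif2tf$motif_id[db$motif2tf$tf == tf]
    enriched <- annotated & !is.na(nes) & nes >= nes_cut
    rows[[tf]] <- data.frame(tf = tf, motif_id = db$motif_ids, auc = auc,
                             nes = nes, annotated = annotated,
                             enriched = enriched, stringsAsFactors = FALSE)
    le[[tf]] <- lapply(stats::setNames(db$motif_ids, db$motif_ids),
                       function(m) S[inT[m, ]])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), motif_id = character(), auc = numeric(),
               nes = numeric(), annotated = logical(), enriched = logical())
  rownames(tab) <- NULL
  structure(list(table = tab, leading_edge = le,
                 rank_threshold = T_, nes_cut = nes_cut),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("motif_enrichment: %d TF x motif tests, %d enriched (NES >= %.1f, top %d ranks)\n",
              nrow(x$table), sum(x$table$enriched), x$nes_cut,
              x$rank_threshold))
  invisible(x)
}

#' Prune candidate edges to the motif-supported regulatory network
#'
#' An edge (tf, target) survives only if the target lies in the leading edge
#' of at least one enriched motif annotated to the TF; the supporting motif
#' with the best NES is attached. TFs with no motif annotation in the
#' database lose all their edges and are flagged.
#'
#' @param candidates candidate edge table from [infer_candidates].
#' @param enrichment a `motif_enrichment` result.
#' @return object of class `grn_fit`: list with `edges` (tf, target,
#'   importance, motif_id, auc, nes), `unannotated_tfs`, `n_candidates`.
#' @export
prune_to_grn <- function(candidates, enrichment) {
  stopifnot(inherits(enrichment, "motif_enrichment"))
  tab <- enrichment$table
  kept <- list()
  tfs <- unique(candidates$tf)
  unann <- character()
  for (tf in tfs) {
    sub <- tab[tab$tf == tf & tab$annotated, , drop = FALSE]
    if (nrow(sub) == 0L) {
      unann <- c(unann, tf)
      next
    }
    enr <- sub[sub$enriched, , drop = FALSE]
    if (nrow(enr) == 0L) next
    enr <- enr[order(-enr$nes), , drop = FALSE]
    cand <- candidates[candidates$tf == tf, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      tg <- cand$target[i]
      for (j in seq_len(nrow(enr))) {
        m <- enr$motif_id[j]
        if (tg %in% enrichment$leading_edge[[tf]][[m]]) {
          kept[[length(kept) + 1L]] <- data.frame(
            tf = tf, target = tg, importance = cand$importance[i],
            motif_id = m, auc = enr$auc[j], nes = enr$nes[j],
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  edges <- if (length(kept)) do.call(rbind, kept) else
    data.frame(tf = character(), target = character(), importance = numeric(),
               motif_id = character(), auc = numeric(), nes = numeric())
  rownames(edges) <- NULL
  if (length(unann) > 0L) {
    warning(sprintf("TF(s) without motif annotation dropped: %s",
                    paste(unann, collapse = ", ")), call. = FALSE)
  }
  structure(list(edges = edges, unannotated_tfs = unann,
                 n_candidates = nrow(candidates)),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("grn_fit: %d motif-supported edges (from %d candidates), %d TFs\n",
              nrow(x$edges), x$n_candidates, length(unique(x$edges$tf))))
  if (length(x$unannotated_tfs) > 0L) {
    cat("unannotated TFs dropped:", paste(x$unannotated_tfs, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Module to regulatory network in one call
#'
#' Scans the module for TFs, infers boosted candidate edges, runs motif
#' enrichment, and prunes to the motif-supported network.
#'
#' @param expr [sc_expr] (original or representative cells).
#' @param module_genes genes of the selected module.
#' @param tf_list known TF symbols.
#' @param db a [motif_db].
#' @param seed integer seed for the boosting.
#' @param rank_threshold_frac,nes_cut motif enrichment controls.
#' @param ... passed to [infer_candidates].
#' @return a `grn_fit`, with the candidate table attached as attribute
#'   `candidates` and the enrichment as `enrichment`.
#' @export
fit_grn <- function(expr, module_genes, tf_list, db, seed = 1L,
                    rank_threshold_frac = 0.05, nes_cut = 3.0, ...) {
  tfs <- scan_tfs(module_genes, tf_list)
  cand <- infer_candidates(expr, tfs, targets = module_genes, seed = seed, ...)
  tf_targets <- split(cand$target, cand$tf)
  enr <- motif_enrichment(tf_targets, db, rank_threshold_frac, nes_cut)
  g <- prune_to_grn(cand, enr)
  attr(g, "candidates") <- cand
  attr(g, "enrichment") <- enr
  g
}
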