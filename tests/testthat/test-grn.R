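# small helper: build a motif_db from explicit rank placements
tiny_db <- function(G, placements, ann, gene_prefix = "g") {
  genes <- sprintf("%s%03d", gene_prefix, seq_len(G))
  ranks <- t(sapply(names(placements), function(m) {
    r <- integer(G)
    pl <- placements[[m]]
    r[match(names(pl), genes)] <- pl
    # unplaced genes get the remaining ranks worst-first, so a gene is only
    # in the top region if the test put it there
    r[r == 0L] <- rev(setdiff(seq_len(G), pl))
    r
  }))
  colnames(ranks) <- genes
  motif_db(ranks, ann)
}

test_that("scan_tfs intersects preserving module order", {
  module <- c("GATA2", "MAFF", "FOSB", "IL6", "TNF")
  tfs <- c("FOSB", "GATA2", "MAFF", "STAT1")
  expect_equal(scan_tfs(module, tfs), c("GATA2", "MAFF", "FOSB"))
  expect_error(scan_tfs(c("IL6", "TNF"), tfs), "no known TFs")
  expect_equal(scan_tfs(c("MAFF", "FOSB"), tfs), c("MAFF", "FOSB"))
})

test_that("boosting recovers a strong linear regulator", {
  for (s in 1:3) {
    set.seed(s)
    n <- 200
    TFs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, sprintf("TF%02d", 1:10)))
    y <- 3 * TFs[, 1] + rnorm(n, sd = 0.1 * sd(TFs[, 1]))
    X <- cbind(TFs, tgt = y)
    cand <- infer_candidates(X, colnames(TFs), "tgt", seed = s,
                             n_trees_max = 300)
    expect_equal(cand$tf[which.max(cand$importance)], "TF01")
  }
})

test_that("no self-edges, and constant inputs yield no candidates", {
  set.seed(30)
  n <- 50
  X <- cbind(TFa = rnorm(n), TFb = rnorm(n))
  X <- cbind(X, tgt = X[, "TFa"] + rnorm(n, sd = 0.1))
  cand <- infer_candidates(X, c("TFa", "TFb", "tgt"), "tgt", seed = 1,
                           n_trees_max = 100)
  expect_false("tgt" %in% cand$tf)

  Xc <- cbind(TFa = rep(1, n), TFb = rep(2, n), tgt = rnorm(n))
  w <- capture_warnings(c2 <- infer_candidates(Xc, c("TFa", "TFb"), "tgt",
                                               seed = 1, n_trees_max = 100))
  expect_match(w, "no candidate edges", all = FALSE)
  expect_equal(nrow(c2), 0)

  w3 <- capture_warnings(c3 <- infer_candidates(cbind(TFa = rnorm(n),
                                                      tgt = rep(5, n)),
                                                "TFa", "tgt", seed = 1))
  expect_match(w3, "constant", all = FALSE)
  expect_equal(nrow(c3), 0)
  expect_error(infer_candidates(X[1:5, ], c("TFa", "TFb"), "tgt"),
               "10 samples")
})

test_that("candidate inference is deterministic for a fixed seed", {
  set.seed(31)
  n <- 60
  X <- cbind(matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("TF", 1:4))),
             tgt = rnorm(n))
  a <- infer_candidates(X, paste0("TF", 1:4), "tgt", seed = 9,
                        n_trees_max = 100)
  b <- infer_candidates(X, paste0("TF", 1:4), "tgt", seed = 9,
                        n_trees_max = 100)
  expect_identical(a, b)
})

test_that("recovery AUC follows its closed form", {
  # set of 3 genes at ranks 1, 2, 3; G = 1000, T = 100
  G <- 1000
  ann <- data.frame(motif_id = "m1", tf = "TF1")
  db <- tiny_db(G, list(m1 = c(g001 = 1L, g002 = 2L, g003 = 3L),
                        m2 = c(g500 = 1L)), ann)
  enr <- motif_enrichment(list(TF1 = c("g001", "g002", "g003")), db,
                          rank_threshold_frac = 0.1)
  auc <- enr$table$auc[enr$table$motif_id == "m1"]
  expect_equal(auc, 0.99)  # (100 + 99 + 98)/(100 * 3)
  expect_equal(auc, oracle_auc(c(1, 2, 3), 100, 3))
  expect_equal(enr$leading_edge$TF1$m1, c("g001", "g002", "g003"))
})

test_that("AUC is 0 with no member in the top region and monotone in rank", {
  G <- 200  # T = 10 at the default 5% threshold
  ann <- data.frame(motif_id = c("far", "near", "nearer"),
                    tf = rep("TF1", 3))
  db <- tiny_db(G, list(far = c(g001 = 150L),
                        near = c(g001 = 9L),
                        nearer = c(g001 = 2L)), ann)
  enr <- motif_enrichment(list(TF1 = "g001"), db)
  tab <- enr$table
  expect_equal(tab$auc[tab$motif_id == "far"], 0)
  expect_gt(tab$auc[tab$motif_id == "nearer"],
            tab$auc[tab$motif_id == "near"])
})

test_that("NES standardizes against all motifs of the database", {
  set.seed(33)
  G <- 100
  placements <- c(list(mA = c(g001 = 1L, g002 = 2L)),
                  lapply(stats::setNames(1:8, paste0("bg", 1:8)),
                         function(i) c(g001 = sample(20:90, 1))))
  ann <- data.frame(motif_id = "mA", tf = "TF1")
  db <- tiny_db(G, placements, ann)
  enr <- motif_enrichment(list(TF1 = c("g001", "g002")), db)
  tab <- enr$table
  expect_equal(mean(tab$nes), 0, tolerance = 1e-12)
  expect_equal(sd(tab$nes), 1, tolerance = 1e-12)
  expect_equal(tab$nes, (tab$auc - mean(tab$auc)) / sd(tab$auc),
               tolerance = 1e-12)
})

test_that("targets missing from the database are dropped with a warning", {
  G <- 50
  ann <- data.frame(motif_id = "m1", tf = "TF1")
  db <- tiny_db(G, list(m1 = c(g001 = 1L), m2 = c(g030 = 1L)), ann)
  expect_warning(enr <- motif_enrichment(list(TF1 = c("g001", "ALIEN")), db),
                 "absent")
  expect_equal(enr$leading_edge$TF1$m1, "g001")
})

test_that("pruning keeps only leading-edge targets of enriched motifs", {
  G <- 100  # T = 5
  # annotated motif covers 3 of the 5 candidate targets within the top T
  ann <- data.frame(motif_id = "m1", tf = "TF1")
  placements <- list(m1 = c(g001 = 1L, g002 = 2L, g003 = 3L))
  # background motifs so that the NES of m1 clears the cut
  for (i in 1:20) {
    placements[[paste0("bg", i)]] <- c(g099 = i + 5L)
  }
  db <- tiny_db(G, placements, ann)
  cand <- data.frame(tf = "TF1",
                     target = sprintf("g%03d", 1:5),
                     importance = 5:1, stringsAsFactors = FALSE)
  enr <- motif_enrichment(split(cand$target, cand$tf), db)
  grn <- prune_to_grn(cand, enr)
  expect_equal(sort(grn$edges$target), c("g001", "g002", "g003"))
  expect_true(all(grn$edges$motif_id == "m1"))
  # retained set is a subset of the candidates
  expect_true(all(paste(grn$edges$tf, grn$edges$target) %in%
                  paste(cand$tf, cand$target)))

  # a TF with no motif annotation loses all edges and is flagged
  cand2 <- data.frame(tf = "TFX", target = "g001", importance = 1)
  enr2 <- motif_enrichment(split(cand2$target, cand2$tf), db)
  expect_warning(grn2 <- prune_to_grn(cand2, enr2), "TFX")
  expect_equal(nrow(grn2$edges), 0)
  expect_equal(grn2$unannotated_tfs, "TFX")
})
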