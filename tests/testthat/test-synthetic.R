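small_sim <- function(seed = 1, loading = 0.8) {
  simulate_counts(n_groups = 2, cells_per_group = 75, blobs_per_group = 3,
                  n_genes = 120, n_modules = 2, module_size = 30,
                  loading = loading, seed = seed)
}

test_that("simulated counts have the declared shape and ground truth", {
  sim <- small_sim()
  expect_equal(dim(sim$expr$values), c(150, 120))
  expect_true(sim$expr$counts)
  expect_equal(length(sim$truth$module_of), 120)
  expect_equal(sum(sim$truth$module_of != 0), 60)
  # driver belongs to its module; regulon is the rest of the module
  for (m in 1:2) {
    tf <- sim$truth$driver_tf[[paste0("M", m)]]
    expect_equal(unname(sim$truth$module_of[tf]), m)
    expect_setequal(c(tf, sim$truth$regulon[[tf]]),
                    names(sim$truth$module_of)[sim$truth$module_of == m])
  }
  expect_error(simulate_counts(n_genes = 50, n_modules = 5,
                               module_size = 20), "exceeds")
})

test_that("module loading drives within-module correlation", {
  sim0 <- small_sim(seed = 2, loading = 0)
  X0 <- log1p(sim0$expr$values)
  mod1 <- names(sim0$truth$module_of)[sim0$truth$module_of == 1]
  C0 <- cor(X0[, mod1[1:15]])
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.1)

  sim <- small_sim(seed = 2, loading = 0.8)
  X <- log1p(sim$expr$values)
  m1 <- names(sim$truth$module_of)[sim$truth$module_of == 1]
  m2 <- names(sim$truth$module_of)[sim$truth$module_of == 2]
  C <- cor(X[, c(m1, m2)])
  within <- c(C[m1, m1][upper.tri(C[m1, m1])],
              C[m2, m2][upper.tri(C[m2, m2])])
  between <- C[m1, m2]
  expect_gte(mean(within) - mean(abs(between)), 0.3)
})

test_that("motif rankings are permutations and favor the true regulon", {
  sim <- small_sim(seed = 3)
  db <- simulate_motif_db(sim$truth, n_motifs = 20, signal_frac = 1.0,
                          seed = 3)
  G <- length(db$gene_ids)
  for (i in seq_len(nrow(db$ranks))) {
    expect_equal(sort(db$ranks[i, ]), seq_len(G), ignore_attr = TRUE)
  }
  tf <- names(sim$truth$regulon)[1]
  reg <- sim$truth$regulon[[tf]]
  enr <- motif_enrichment(stats::setNames(list(reg), tf), db)
  tab <- enr$table
  true_auc <- tab$auc[tab$motif_id == paste0("motif_true_", tf)]
  expect_gte(true_auc, max(tab$auc[grepl("decoy", tab$motif_id)]))
})

test_that("without signal the true motif is indistinguishable from decoys", {
  sim <- small_sim(seed = 4)
  below <- 0L
  for (s in 1:20) {
    db <- simulate_motif_db(sim$truth, n_motifs = 20, signal_frac = 0,
                            seed = s)
    tf <- names(sim$truth$regulon)[1]
    enr <- motif_enrichment(stats::setNames(list(sim$truth$regulon[[tf]]),
                                            tf), db)
    tab <- enr$table
    nes <- tab$nes[tab$motif_id == paste0("motif_true_", tf)]
    if (is.na(nes) || nes < 3) below <- below + 1L
  }
  expect_gte(below / 20, 0.9)
})

test_that("drug table simulation is seed-deterministic and in-universe", {
  genes <- sprintf("g%03d", 1:50)
  a <- simulate_drug_table(genes, n_drugs = 10, seed = 7)
  b <- simulate_drug_table(genes, n_drugs = 10, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$gene_symbol %in% genes))
  expect_error(simulate_drug_table(genes, n_drugs = 0), ">= 1")
})

test_that("fixture files are byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  args <- list(seed = 5, n_groups = 1, cells_per_group = 40,
               blobs_per_group = 2, n_genes = 60, n_modules = 2,
               module_size = 15)
  do.call(write_synthetic_scenario, c(list(dir = d1), args))
  do.call(write_synthetic_scenario, c(list(dir = d2), args))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_setequal(list.files(d1),
                  c("counts.tsv", "metadata.tsv", "tfs.txt",
                    "motif_ranks.tsv", "motif2tf.tsv", "drugs.tsv"))
})
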