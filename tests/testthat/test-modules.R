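fit_small_gcn <- function(X, power = 6, min_module_size = 10,
                          cut_height = NULL) {
  e <- sc_expr(X)
  suppressWarnings(suppressMessages(
    fit_gcn(e, power = power, min_module_size = min_module_size,
            cut_height = cut_height)))
}

test_that("three perfectly correlated blocks give exactly three modules", {
  # within-block correlation 1 (dissimilarity ~0), between-block ~0: the
  # blocks merge only near the very top of the tree, so any mid-range cut
  # separates them
  X <- make_block_expression(25, c(35, 33, 31), seed = 2, orthogonal = TRUE)
  g <- fit_small_gcn(X, power = 6, min_module_size = 30, cut_height = 0.9)
  labels <- g$modules$labels
  expect_equal(length(unique(labels[labels != 0])), 3)
  expect_equal(sum(labels == 0), 0)
  # labels match the planted blocks up to permutation
  planted <- sub("g.*$", "", names(labels))
  expect_equal(length(unique(paste(planted, labels))), 3)
})

test_that("pure i.i.d. noise leaves at least 90% of genes unassigned", {
  set.seed(42)
  X <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(NULL, sprintf("g%03d", 1:100)))
  g <- suppressWarnings(fit_gcn(sc_expr(X)))
  expect_gte(mean(g$modules$labels == 0), 0.9)
})

test_that("module labels are invariant under gene permutation", {
  skip_if_not_installed("mclust")
  X <- make_block_expression(25, c(14, 12, 10), n_noise = 6, seed = 5)
  perm <- withr::with_seed(9, sample(ncol(X)))
  run <- function(M) {
    C <- suppressMessages(correlation_matrix(M, "bicor"))
    A <- adjacency_matrix(C, "signed", 6)
    detect_modules(tom_similarity(A), M, min_module_size = 8)$labels
  }
  l1 <- run(X)
  l2 <- run(X[, perm])
  expect_equal(mclust::adjustedRandIndex(l1, l2[names(l1)]), 1)
})

test_that("eigengene of identical genes explains all variance, sign +", {
  set.seed(3)
  v <- rnorm(20)
  X <- matrix(rep(v, 5), 20, 5, dimnames = list(NULL, paste0("g", 1:5)))
  labels <- stats::setNames(rep(1L, 5), colnames(X))
  eg <- module_eigengenes(X, labels)
  expect_equal(unname(eg$var_explained), 1, tolerance = 1e-12)
  expect_equal(unname(cor(eg$eigengenes[, "ME1"], v)), 1, tolerance = 1e-9)
})

test_that("antisymmetric two-gene module: full variance, mean kME >= 0", {
  set.seed(4)
  x <- rnorm(15)
  X <- cbind(a = x, b = -x)
  labels <- stats::setNames(c(1L, 1L), c("a", "b"))
  eg <- module_eigengenes(X, labels)
  expect_equal(unname(eg$var_explained), 1, tolerance = 1e-12)
  kME <- module_membership(X, eg$eigengenes, labels, method = "pearson")
  expect_gte(mean(kME), 0)
})

test_that("var_explained matches an independent eigendecomposition", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("g", 1:10)))
  labels <- stats::setNames(rep(1L, 10), colnames(X))
  eg <- module_eigengenes(X, labels)
  expect_equal(unname(eg$var_explained), oracle_var_explained(X),
               tolerance = 1e-9)
})

test_that("trait correlation: identity, independence, and matrix shape", {
  set.seed(5)
  n <- 200
  cond <- rep(c("sick", "well"), each = n / 2)
  e1 <- as.numeric(cond == "sick")       # eigengene = indicator
  e2 <- rnorm(n)                         # independent of the trait
  ME <- cbind(ME1 = e1, ME2 = e2)
  md <- data.frame(cell_id = as.character(1:n), condition = cond)
  tc <- module_trait_correlation(ME, md)
  r11 <- tc[tc$module == "ME1" & tc$trait == "condition.sick", ]
  expect_equal(r11$rho, 1, tolerance = 1e-12)
  r2 <- tc[tc$module == "ME2" & tc$trait == "condition.sick", ]
  expect_lt(abs(r2$rho), 0.2)
  expect_gt(r2$p_adj, 0.05)
  # adjusted p never below raw p
  expect_true(all(tc$p_adj >= tc$p - 1e-15))

  # 27 modules x 3 one-hot conditions -> 81 cells in the long table
  ME27 <- matrix(rnorm(30 * 27), 30, 27,
                 dimnames = list(NULL, paste0("ME", 1:27)))
  md3 <- data.frame(cell_id = as.character(1:30),
                    condition = rep(c("healthy", "deceased", "surviving"), 10))
  tc27 <- module_trait_correlation(ME27, md3)
  expect_equal(nrow(tc27), 27 * 3)
  expect_equal(length(unique(tc27$module)), 27)
  expect_equal(length(unique(tc27$trait)), 3)
})

test_that("constant traits are flagged with zero correlation", {
  ME <- cbind(ME1 = rnorm(10))
  md <- data.frame(cell_id = as.character(1:10), flat = rep("x", 10))
  expect_warning(tc <- module_trait_correlation(ME, md), "constant")
  expect_equal(tc$rho, 0)
  expect_true(tc$constant)
})

test_that("kIM: complete module gives k = m - 1 and matches the oracle", {
  A5 <- matrix(1, 5, 5); diag(A5) <- 0
  dimnames(A5) <- list(paste0("g", 1:5), paste0("g", 1:5))
  labels <- stats::setNames(rep(1L, 5), paste0("g", 1:5))
  expect_equal(unname(intramodular_connectivity(A5, labels)), rep(4, 5))

  set.seed(11)
  n <- 12
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
  dimnames(A) <- list(paste0("g", 1:n), paste0("g", 1:n))
  labels <- stats::setNames(rep(c(1L, 2L, 0L), each = 4), paste0("g", 1:n))
  expect_equal(intramodular_connectivity(A, labels), oracle_kim(A, labels),
               tolerance = 1e-12)
  expect_equal(unname(intramodular_connectivity(A, labels)[9:12]), rep(0, 4))
})

test_that("kME of a gene equal to its eigengene is 1", {
  set.seed(12)
  e <- rnorm(20)
  X <- cbind(g1 = e, g2 = e + rnorm(20, sd = 0.2))
  labels <- stats::setNames(c(1L, 1L), c("g1", "g2"))
  ME <- cbind(ME1 = e)
  kME <- module_membership(X, ME, labels, method = "pearson")
  expect_equal(unname(kME["g1"]), 1, tolerance = 1e-12)
})

test_that("hub rule: concordant rankings intersect, reversed do not", {
  genes <- sprintf("g%02d", 1:20)
  kIM <- stats::setNames(20:1, genes)
  kME_same <- stats::setNames(seq(1, 0.05, length.out = 20), genes)
  hubs <- detect_hubs(genes, kIM, kME_same)
  expect_equal(hubs, c("g01", "g02"))     # top 10% of 20 = 2 genes
  kME_rev <- stats::setNames(seq(0.05, 1, length.out = 20), genes)
  expect_equal(detect_hubs(genes, kIM, kME_rev), character())
  expect_warning(detect_hubs("g01", kIM, kME_same), "fewer than 2")
})

test_that("submodule extraction honors the correlation threshold", {
  # 90-gene module in which exactly 16 genes form a >= 0.9 clique
  set.seed(16)
  n <- 60
  base <- rnorm(n)
  clique <- sapply(1:16, function(i) base + rnorm(n, sd = 0.15))
  weak <- sapply(1:74, function(i) 0.5 * base + rnorm(n, sd = 1))
  X <- cbind(clique, weak)
  colnames(X) <- sprintf("g%02d", 1:90)
  C <- cor(X)
  sub <- extract_submodule(C, colnames(X), 0.9)
  expect_equal(sort(sub$genes), sprintf("g%02d", 1:16))

  all_edges <- extract_submodule(C, colnames(X), 0, signed = FALSE)
  expect_equal(nrow(all_edges$edges), 90 * 89 / 2)
  expect_equal(length(all_edges$genes), 90)
  none <- extract_submodule(C, colnames(X), 1 + 1e-9)
  expect_equal(length(none$genes), 0)
})
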