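# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately re-derive each quantity from its
# definition with naive loops.

# biweight midcorrelation by direct evaluation of the defining formula
oracle_bicor <- function(x, y) {
  tilde <- function(v) {
    m <- median(v)
    mad0 <- median(abs(v - m))
    u <- (v - m) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - m) * w
  }
  xt <- tilde(x); yt <- tilde(y)
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

# topological overlap by triple loop
oracle_tom <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    out[i, j] <- (s + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# intramodular connectivity by explicit per-gene summation
oracle_kim <- function(A, labels) {
  genes <- colnames(A)
  sapply(genes, function(g) {
    m <- labels[g]
    if (m == 0) return(0)
    partners <- setdiff(genes[labels == m], g)
    sum(A[g, partners])
  })
}

# leading-eigenvalue variance fraction via eigen() on the covariance
oracle_var_explained <- function(X_module) {
  Z <- scale(X_module)
  ev <- eigen(stats::cov(Z), symmetric = TRUE, only.values = TRUE)$values
  ev[1] / sum(ev)
}

# recovery AUC by literally accumulating the step curve c(r)
oracle_auc <- function(ranks_of_set, T_, set_size) {
  total <- 0
  for (r in seq_len(T_)) total <- total + sum(ranks_of_set <= r)
  total / (T_ * set_size)
}

# small deterministic expression fixture with planted identical-gene blocks;
# orthogonal = TRUE makes between-block correlation exactly zero
make_block_expression <- function(n_samples, block_sizes, n_noise = 0,
                                  seed = 1, orthogonal = FALSE) {
  set.seed(seed)
  bases <- matrix(rnorm(n_samples * length(block_sizes)), n_samples)
  if (orthogonal) {
    # center first so the orthonormal combinations stay mean-zero, making
    # between-block Pearson correlation exactly zero
    bases <- sweep(bases, 2, colMeans(bases))
    bases <- qr.Q(qr(bases))
  }
  cols <- list()
  nm <- character()
  for (b in seq_along(block_sizes)) {
    base <- bases[, b]
    for (g in seq_len(block_sizes[b])) {
      cols[[length(cols) + 1L]] <- base
      nm <- c(nm, sprintf("b%dg%02d", b, g))
    }
  }
  for (g in seq_len(n_noise)) {
    cols[[length(cols) + 1L]] <- rnorm(n_samples)
    nm <- c(nm, sprintf("noise%02d", g))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}
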