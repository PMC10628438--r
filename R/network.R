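#' Soft-thresholded adjacency from a correlation matrix
#'
#' Raises (transformed) correlations to the soft power beta. Network types:
#' `unsigned` a = |cor|^beta; `signed` a = ((1 + cor)/2)^beta (preserves
#' correlation signs, the default network for module inference);
#' `signed_hybrid` a = cor^beta for positive correlations and 0 otherwise
#' (all negative correlation coefficients are treated as zero). The diagonal
#' is set to zero so that connectivity k_i = sum_j a_ij excludes self.
#'
#' @param cor symmetric correlation matrix from [correlation_matrix].
#' @param network_type `"signed"` (default), `"signed_hybrid"`, `"unsigned"`.
#' @param beta soft power, >= 1.
#' @return adjacency matrix with entries in \[0, 1\], zero diagonal,
#'   attributes `network_type` and `beta`.
#' @export
adjacency_matrix <- function(cor,
                             network_type = c("signed", "signed_hybrid",
                                              "unsigned"),
                             beta = 6) {
  network_type <- match.arg(network_type)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  A <- switch(network_type,
    unsigned      = abs(cor)^beta,
    signed        = ((1 + cor) / 2)^beta,
    signed_hybrid = ifelse(cor > 0, cor^beta, 0))
  diag(A) <- 0
  attr(A, "network_type") <- network_type
  attr(A, "beta") <- beta
  A
}

connectivity <- function(adj) rowSums(adj)

#' Scale-free topology fit of the connectivity distribution
#'
#' Bins connectivities k_i = sum_{j != i} a_ij into `n_bins` equal-width
#' bins and fits ordinary least squares of log10 frequency on log10 mean
#' connectivity over the non-empty bins. The fit index is R^2 signed by the
#' negated slope sign, so a scale-free-like decreasing distribution yields a
#' positive value.
#'
#' @param adj adjacency matrix (or a precomputed connectivity vector).
#' @param n_bins number of equal-width connectivity bins (default 10).
#' @return list of class `scale_free_fit` with `r2`, `slope`, `n_bins`,
#'   `fit_data` (per-bin mean k and frequency).
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- if (is.matrix(adj)) connectivity(adj) else as.numeric(adj)
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (length(unique(brk)) < 2L) {
    stop("degenerate connectivity distribution: all values equal",
         call. = FALSE)
  }
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k) & !is.na(freq) & mean_k > 0 & freq > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 non-empty connectivity bins; cannot assess fit",
         call. = FALSE)
  }
  lx <- log10(mean_k[keep]); ly <- log10(freq[keep])
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared * (-sign(slope))
  structure(list(r2 = r2, slope = slope, n_bins = n_bins,
                 fit_data = data.frame(log10_k = unname(lx),
                                       log10_p = unname(ly))),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale-free fit: signed R^2 = %.3f, slope = %.3f (%d bins)\n",
              x$r2, x$slope, x$n_bins))
  invisible(x)
}

#' Choose the soft-threshold power
#'
#' Evaluates candidate powers, computing the signed scale-free fit index and
#' connectivity summaries for each, and returns the smallest power whose fit
#' index reaches `r2_cut`. If none qualifies, the connectivity distribution
#' is effectively not scale-free and the fit index carries little signal;
#' when `n_samples` is supplied the conventional sample-size-based default
#' power for the network type is used instead (and flagged), because picking
#' the maximal fit index in that regime chases noise. Without `n_samples`
#' the power with the maximal fit index is returned, flagged.
#'
#' @param cor correlation matrix.
#' @param network_type adjacency variant, see [adjacency_matrix].
#' @param powers candidate powers (default 1..20).
#' @param r2_cut fit-index threshold (default 0.85).
#' @param n_bins bins for the fit.
#' @param n_samples number of samples behind `cor`; enables the recommended
#'   fallback power when no candidate reaches `r2_cut`.
#' @return list of class `soft_threshold`: `power`, `reached_cut` (logical),
#'   `table` (power, r2, slope, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(cor,
                                network_type = c("signed", "signed_hybrid",
                                                 "unsigned"),
                                powers = 1:20, r2_cut = 0.85, n_bins = 10,
                                n_samples = NULL) {
  network_type <- match.arg(network_type)
  if (length(powers) == 0L) stop("powers must be non-empty", call. = FALSE)
  rows <- lapply(powers, function(b) {
    A <- adjacency_matrix(cor, network_type, b)
    k <- connectivity(A)
    sf <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NULL)
    data.frame(power = b,
               r2 = if (is.null(sf)) NA_real_ else sf$r2,
               slope = if (is.null(sf)) NA_real_ else sf$slope,
               mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2) & tab$r2 >= r2_cut)
  if (length(ok) > 0L) {
    power <- tab$power[ok[1]]
    reached <- TRUE
  } else {
    reached <- FALSE
    if (!is.null(n_samples)) {
      rec <- recommended_power(n_samples, network_type)
      power <- powers[which.min(abs(powers - rec))]
      warning(sprintf(
        "no power reached fit index %.2f; using the recommended default %d for %d samples (%s network)",
        r2_cut, power, n_samples, network_type), call. = FALSE)
    } else {
      best <- which.max(tab$r2)
      power <- if (length(best) > 0L) tab$power[best] else powers[1]
      warning(sprintf(
        "no power reached fit index %.2f; using power %d (max r2 = %.3f)",
        r2_cut, power, suppressWarnings(max(tab$r2, na.rm = TRUE))),
        call. = FALSE)
    }
  }
  structure(list(power = power, reached_cut = reached, table = tab),
            class = "soft_threshold")
}

# conventional default powers by sample count when the scale-free fit is
# uninformative (the published usage guideline of this network family)
recommended_power <- function(n_samples, network_type) {
  signed <- network_type == "signed"
  if (n_samples < 20) return(if (signed) 18 else 9)
  if (n_samples < 30) return(if (signed) 16 else 8)
  if (n_samples < 40) return(if (signed) 14 else 7)
  if (signed) 12 else 6
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("soft threshold: power = %d (%s)\n", x$power,
              if (x$reached_cut) "fit cut reached" else "best available fit"))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j
#' (the sum excludes u in \{i, j\}), TOM_ii = 1. Measures how much two genes
#' share neighbors on top of their direct adjacency; 1 - TOM is the
#' clustering dissimilarity.
#'
#' @param adj adjacency matrix with zero diagonal and entries in \[0, 1\].
#' @return symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (any(adj < 0) || any(adj > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  A <- adj
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A           # (i,j) entry = sum_u a_iu a_uj, u != i, j since diag 0
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(adj)
  TOM
}
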