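#' Biweight midcorrelation of two vectors
#'
#' Robust correlation based on the median: with u_i = (x_i - med(x)) /
#' (9 * mad(x)) (mad unscaled), weights w_i = (1 - u_i^2)^2 for |u_i| < 1 and
#' 0 otherwise, and x~_i = (x_i - med(x)) * w_i, the correlation is
#' sum(x~ y~) / sqrt(sum(x~^2) * sum(y~^2)). Less sensitive to outliers than
#' Pearson's r. Falls back to Pearson when either vector has zero median
#' absolute deviation.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y))
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  if (is.null(tx) || is.null(ty)) {
    message("bicor: zero median absolute deviation, falling back to Pearson")
    return(cor(x, y))
  }
  sum(tx * ty)
}

# Returns the unit-normalized bicor-weighted deviations, or NULL if mad = 0.
bicor_transform <- function(x) {
  m <- median(x)
  mad0 <- median(abs(x - m))
  if (mad0 == 0) return(NULL)
  u <- (x - m) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - m) * w
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) return(NULL)
  xt / nrm
}

#' Gene-gene correlation matrix
#'
#' Computes all pairwise correlations between genes (columns) across samples
#' (rows). For `method = "bicor"` genes whose unscaled median absolute
#' deviation is zero fall back to Pearson for all their pairs (reported via a
#' message). Zero-variance genes under Pearson/Spearman get correlation 0
#' with a warning.
#'
#' @param expr an [sc_expr] object or a samples x genes numeric matrix.
#' @param method one of `"bicor"` (default), `"pearson"`, `"spearman"`.
#' @return symmetric genes x genes matrix with unit diagonal and a `method`
#'   attribute.
#' @export
correlation_matrix <- function(expr, method = c("bicor", "pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(expr, "sc_expr")) expr$values else as.matrix(expr)
  if (nrow(X) < 3L) {
    stop("correlation requires at least 3 samples", call. = FALSE)
  }
  zero_var <- apply(X, 2, var) == 0
  if (method %in% c("pearson", "spearman")) {
    # zero-variance columns are handled explicitly below
    C <- suppressWarnings(cor(X, method = method))
    C[!is.finite(C)] <- 0
    if (any(zero_var)) {
      warning(sprintf("%d zero-variance genes; their correlations set to 0",
                      sum(zero_var)), call. = FALSE)
      C[zero_var, ] <- 0
      C[, zero_var] <- 0
    }
  } else {
    TT <- matrix(0, nrow(X), ncol(X))
    degenerate <- logical(ncol(X))
    for (j in seq_len(ncol(X))) {
      tj <- bicor_transform(X[, j])
      if (is.null(tj)) degenerate[j] <- TRUE else TT[, j] <- tj
    }
    C <- crossprod(TT)
    if (any(degenerate)) {
      message(sprintf(
        "bicor: %d gene(s) with zero mad fall back to Pearson for their pairs",
        sum(degenerate)))
      P <- cor(X)
      P[!is.finite(P)] <- 0
      C[degenerate, ] <- P[degenerate, , drop = FALSE]
      C[, degenerate] <- P[, degenerate, drop = FALSE]
    }
    if (any(zero_var)) {
      C[zero_var, ] <- 0
      C[, zero_var] <- 0
    }
  }
  C[C > 1] <- 1
  C[C < -1] <- -1
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(colnames(X), colnames(X))
  attr(C, "method") <- method
  C
}
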