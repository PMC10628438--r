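#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test cutree hclust kmeans lm median p.adjust
#'   prcomp predict quantile rnbinom rnorm runif sd var as.dist coef
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local, restorable RNG state so package functions are
# deterministic under `seed` without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(head(dup, 10L), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' Area under the precision-recall curve by average precision
#'
#' Step-wise average precision: precision at each positive hit, averaged over
#' all positives, with scores sorted decreasingly (ties broken by input order).
#' Used to benchmark candidate-edge importances against a planted edge set.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels logical (or 0/1) vector of the same length; TRUE = positive.
#' @return scalar average precision in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels)) return(0)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  hits <- cumsum(lab)
  prec_at_hit <- hits[lab] / which(lab)
  mean(prec_at_hit)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
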