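#' Construct a single-cell expression container
#'
#' Canonical in-memory layout is cells in rows and genes in columns. Cell and
#' gene identifiers must be unique (case-sensitive, matched exactly); the
#' per-cell metadata table is aligned to the cell order.
#'
#' @param values numeric matrix, cells x genes. All values must be finite.
#' @param gene_ids character vector of gene symbols (defaults to colnames).
#' @param cell_ids character vector of cell identifiers (defaults to rownames).
#' @param metadata optional data.frame of per-cell annotations; either one row
#'   per cell in matrix order, or keyed by a `cell_id` column / rownames.
#' @param counts logical; if TRUE the values are checked to be non-negative
#'   integers (raw counts mode).
#' @return an object of class `sc_expr`: a list with elements `values`,
#'   `gene_ids`, `cell_ids`, `metadata`, `counts`.
#' @export
sc_expr <- function(values, gene_ids = colnames(values),
                    cell_ids = rownames(values), metadata = NULL,
                    counts = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("gene_ids length does not match number of columns", call. = FALSE)
  }
  if (length(cell_ids) != nrow(values)) {
    stop("cell_ids length does not match number of rows", call. = FALSE)
  }
  stop_if_duplicates(gene_ids, "gene_ids")
  stop_if_duplicates(cell_ids, "cell_ids")
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (counts && (any(values < 0) || any(values != round(values)))) {
    stop("counts mode requires non-negative integer values", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  if (!is.null(metadata)) {
    metadata <- align_metadata(metadata, cell_ids)
  }
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 metadata = metadata, counts = counts),
            class = "sc_expr")
}

align_metadata <- function(metadata, cell_ids) {
  metadata <- as.data.frame(metadata)
  if ("cell_id" %in% names(metadata)) {
    stop_if_duplicates(metadata$cell_id, "metadata cell_id")
    extra <- setdiff(metadata$cell_id, cell_ids)
    if (length(extra) > 0L) {
      warning(sprintf("%d metadata cells absent from the matrix: %s",
                      length(extra), paste(head(extra, 5L), collapse = ", ")),
              call. = FALSE)
    }
    missing <- setdiff(cell_ids, metadata$cell_id)
    if (length(missing) > 0L) {
      stop(sprintf("metadata lacks %d cells present in the matrix (e.g. %s)",
                   length(missing), paste(head(missing, 5L), collapse = ", ")),
           call. = FALSE)
    }
    metadata <- metadata[match(cell_ids, metadata$cell_id), , drop = FALSE]
  } else {
    if (nrow(metadata) != length(cell_ids)) {
      stop("metadata rows do not match number of cells", call. = FALSE)
    }
    metadata <- cbind(cell_id = cell_ids, metadata)
  }
  rownames(metadata) <- metadata$cell_id
  metadata
}

#' @export
print.sc_expr <- function(x, ...) {
  cat(sprintf("sc_expr: %d cells x %d genes (%s)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (isTRUE(x$counts)) "counts" else "normalized"))
  if (!is.null(x$metadata)) {
    cat("metadata columns:", paste(setdiff(names(x$metadata), "cell_id"),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.sc_expr <- function(x) dim(x$values)

#' Library-size normalization and log transform
#'
#' Scales each cell to `scale_factor` total counts (counts per 10^4 by
#' default) and applies log1p. Cells with zero total count are left at zero
#' with a warning.
#'
#' @param x an `sc_expr` object (typically raw counts).
#' @param scale_factor target total per cell; default 1e4.
#' @return an `sc_expr` with normalized values (`counts = FALSE`).
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "sc_expr"))
  tot <- rowSums(x$values)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d cells have zero total counts", sum(zero)),
            call. = FALSE)
    tot[zero] <- 1
  }
  vals <- log1p(x$values / tot * scale_factor)
  sc_expr(vals, x$gene_ids, x$cell_ids, x$metadata, counts = FALSE)
}
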