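#' Read an expression matrix from disk
#'
#' Supports dense CSV/TSV (first row and first column hold identifiers) and
#' MatrixMarket triplet files with gene/cell identifier sidecars. Whatever the
#' on-disk orientation, the result is returned in the canonical cells-in-rows
#' layout. Lines starting with `#` are treated as comments in CSV/TSV.
#'
#' @param path path to the matrix file.
#' @param fmt one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param orientation layout of the file: `"cells_by_genes"` (rows are cells)
#'   or `"genes_by_cells"` (rows are genes; the matrix is transposed on read).
#' @param genes_path,cells_path sidecar identifier files for `fmt = "mtx"`;
#'   default to `genes.tsv` and `barcodes.tsv` next to the matrix. Each holds
#'   one identifier per line (first column if tab-separated).
#' @param counts logical, enforce the non-negative-integer counts invariant.
#' @return an [sc_expr] object.
#' @export
read_expression <- function(path,
                            fmt = c("tsv", "csv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            genes_path = NULL, cells_path = NULL,
                            counts = FALSE) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (fmt == "mtx") {
    genes_path <- genes_path %||% file.path(dirname(path), "genes.tsv")
    cells_path <- cells_path %||% file.path(dirname(path), "barcodes.tsv")
    for (p in c(path, genes_path, cells_path)) {
      if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    read_ids <- function(p) {
      x <- readLines(p)
      x <- x[nzchar(x) & !startsWith(x, "#")]
      vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
    }
    row_ids <- if (orientation == "cells_by_genes") read_ids(cells_path) else read_ids(genes_path)
    col_ids <- if (orientation == "cells_by_genes") read_ids(genes_path) else read_ids(cells_path)
    if (nrow(m) != length(row_ids) || ncol(m) != length(col_ids)) {
      stop(sprintf("matrix is %d x %d but sidecars give %d x %d identifiers",
                   nrow(m), ncol(m), length(row_ids), length(col_ids)),
           call. = FALSE)
    }
    dimnames(m) <- list(row_ids, col_ids)
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE, comment.char = "#")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  if (orientation == "genes_by_cells") m <- t(m)
  sc_expr(m, gene_ids = colnames(m), cell_ids = rownames(m), counts = counts)
}

#' Write an expression matrix as TSV (cells in rows)
#'
#' @param x an [sc_expr] object.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "sc_expr"))
  df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a per-cell metadata table
#'
#' @param path TSV path; `#` lines are comments.
#' @param key_column name of the column holding cell identifiers.
#' @param cell_ids optional cell identifiers of the matrix the metadata will
#'   be joined to; unmatched metadata cells are reported with a warning (rows
#'   are kept, to be dropped at join time).
#' @return data.frame with a `cell_id` column first.
#' @export
read_metadata <- function(path, key_column = "cell_id", cell_ids = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  if (!key_column %in% names(df)) {
    stop(sprintf("key column '%s' not found in %s", key_column, path),
         call. = FALSE)
  }
  keys <- as.character(df[[key_column]])
  stop_if_duplicates(keys, sprintf("metadata %s", key_column))
  names(df)[names(df) == key_column] <- "cell_id"
  df <- df[, c("cell_id", setdiff(names(df), "cell_id")), drop = FALSE]
  if (!is.null(cell_ids)) {
    extra <- setdiff(df$cell_id, cell_ids)
    if (length(extra) > 0L) {
      warning(sprintf("%d metadata cells not present in matrix: %s",
                      length(extra), paste(head(extra, 5L), collapse = ", ")),
              call. = FALSE)
    }
  }
  df
}

#' Read a transcription-factor symbol list
#'
#' One symbol per line; blank lines skipped; duplicates removed keeping the
#' first occurrence; order preserved.
#'
#' @param path text file path.
#' @return character vector of TF symbols.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- x[!duplicated(x)]
  if (length(x) == 0L) {
    stop(sprintf("TF list '%s' is empty", path), call. = FALSE)
  }
  x
}

#' Construct a motif ranking database
#'
#' Holds a motifs x genes matrix of integer ranks (each row a permutation of
#' 1..G; rank 1 = best-scoring regulatory region for that motif) plus the
#' motif-to-TF annotation used to decide which enriched motifs support a TF.
#'
#' @param ranks integer matrix, motifs x genes, with motif rownames and gene
#'   colnames.
#' @param motif2tf data.frame with columns `motif_id`, `tf`.
#' @return object of class `motif_db`.
#' @export
motif_db <- function(ranks, motif2tf) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  G <- ncol(ranks)
  stop_if_duplicates(rownames(ranks), "motif_ids")
  stop_if_duplicates(colnames(ranks), "motif db gene_ids")
  for (i in seq_len(nrow(ranks))) {
    r <- sort(ranks[i, ])
    if (!identical(as.integer(r), seq_len(G))) {
      stop(sprintf("motif %s: ranks not a permutation of 1..%d",
                   rownames(ranks)[i], G), call. = FALSE)
    }
  }
  motif2tf <- as.data.frame(motif2tf)
  if (!all(c("motif_id", "tf") %in% names(motif2tf))) {
    stop("motif2tf must have columns motif_id and tf", call. = FALSE)
  }
  unknown <- setdiff(motif2tf$motif_id, rownames(ranks))
  if (length(unknown) > 0L) {
    stop(sprintf("annotation references unknown motifs: %s",
                 paste(head(unknown, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(list(ranks = ranks, motif_ids = rownames(ranks),
                 gene_ids = colnames(ranks), motif2tf = motif2tf),
            class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  cat(sprintf("motif_db: %d motifs x %d genes, %d motif-TF annotations\n",
              length(x$motif_ids), length(x$gene_ids), nrow(x$motif2tf)))
  invisible(x)
}

#' Read a motif ranking database from TSV files
#'
#' @param ranks_path TSV with a `motif_id` column then one column per gene;
#'   one row per motif, integer ranks forming a permutation of 1..G.
#' @param annotation_path TSV with columns `motif_id`, `tf`.
#' @return a [motif_db] object.
#' @export
read_motif_db <- function(ranks_path, annotation_path) {
  rk <- read.delim(ranks_path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#")
  if (names(rk)[1] != "motif_id") {
    stop("ranks file must have motif_id as its first column", call. = FALSE)
  }
  m <- as.matrix(rk[, -1, drop = FALSE])
  rownames(m) <- rk$motif_id
  ann <- read.delim(annotation_path, sep = "\t", header = TRUE,
                    check.names = FALSE, comment.char = "#")
  motif_db(m, ann)
}

#' Write a motif ranking database to TSV files
#' @param db a [motif_db] object.
#' @param ranks_path,annotation_path output paths.
#' @export
write_motif_db <- function(db, ranks_path, annotation_path) {
  df <- data.frame(motif_id = db$motif_ids, db$ranks, check.names = FALSE)
  write_tsv(df, ranks_path)
  write_tsv(db$motif2tf, annotation_path)
  invisible(NULL)
}

#' Read a drug-target table
#'
#' Local snapshot of drug-target links with columns `drug_id`, `drug_name`,
#' `gene_symbol`, `action`, `source`. (drug_id, gene_symbol) pairs must be
#' unique; empty drug or gene identifiers are rejected. A `# provenance:`
#' comment line, if present, is carried along as the `provenance` attribute
#' and echoed into outputs.
#'
#' @param path TSV path.
#' @return data.frame of class `drug_table`.
#' @export
read_drug_table <- function(path) {
  first <- readLines(path, n = 5L)
  prov <- grep("^#\\s*provenance:", first, value = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  drug_table(df, provenance = if (length(prov)) {
    trimws(sub("^#\\s*provenance:", "", prov[1]))
  } else NA_character_)
}

#' Construct and validate a drug-target table
#' @param df data.frame with columns drug_id, drug_name, gene_symbol, action,
#'   source.
#' @param provenance free-text snapshot identifier.
#' @return validated data.frame of class `drug_table`.
#' @export
drug_table <- function(df, provenance = NA_character_) {
  need <- c("drug_id", "drug_name", "gene_symbol", "action", "source")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("drug table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(df$drug_id)) || any(!nzchar(df$gene_symbol))) {
    stop("drug table has empty drug_id or gene_symbol entries", call. = FALSE)
  }
  stop_if_duplicates(paste(df$drug_id, df$gene_symbol, sep = "\r"),
                     "(drug_id, gene_symbol) pairs")
  attr(df, "provenance") <- provenance
  class(df) <- c("drug_table", "data.frame")
  df
}

#' Write a typed edge table as TSV
#'
#' Rows are sorted lexicographically by the first column (then the second)
#' so that writes are byte-stable.
#'
#' @param edges data.frame of edges; endpoints in the first two columns.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges[[1]], edges[[2]]), , drop = FALSE]
  }
  write_tsv(edges, path)
}

#' Write a typed network as GraphML
#'
#' Every node must carry a `node_type` attribute in \{gene, tf, drug\}.
#'
#' @param graph an igraph object.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  nt <- igraph::vertex_attr(graph, "node_type")
  if (is.null(nt) || any(!nt %in% c("gene", "tf", "drug"))) {
    stop("all nodes need a node_type attribute in {gene, tf, drug}",
         call. = FALSE)
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_graphml]
#' @param path GraphML file path.
#' @return an igraph object.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
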