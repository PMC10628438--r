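#' Map drugs onto a gene set
#'
#' Joins a local drug-target snapshot table onto a query gene set by exact
#' symbol match and summarizes the number of distinct drugs and distinct
#' targeted genes. Works for whole modules, hub sets or regulatory-network
#' nodes alike.
#'
#' @param genes query gene symbols (module genes, hubs, or GRN nodes).
#' @param table a [drug_table].
#' @return list of class `drug_map`: `associations` (table rows hitting the
#'   query set), `n_drugs`, `n_targeted_genes`, `provenance`.
#' @export
map_drugs <- function(genes, table) {
  stopifnot(inherits(table, "drug_table"))
  if (nrow(table) == 0L) {
    stop("drug-target table is empty", call. = FALSE)
  }
  hit <- table[table$gene_symbol %in% genes, , drop = FALSE]
  rownames(hit) <- NULL
  structure(list(associations = hit,
                 n_drugs = length(unique(hit$drug_id)),
                 n_targeted_genes = length(unique(hit$gene_symbol)),
                 provenance = attr(table, "provenance")),
            class = "drug_map")
}

#' @export
print.drug_map <- function(x, ...) {
  cat(sprintf("drug_map: %d associations; %d distinct drugs over %d targeted genes\n",
              nrow(x$associations), x$n_drugs, x$n_targeted_genes))
  if (!is.na(x$provenance %||% NA)) cat("snapshot:", x$provenance, "\n")
  invisible(x)
}

#' Combined gene/TF/drug network
#'
#' Merges directed regulatory (or undirected module co-expression) edges
#' with drug-target associations into one typed graph: nodes carry a
#' `node_type` attribute in \{gene, tf, drug\} (drug node ids are prefixed
#' `drug:` to keep ids unique across types), regulatory edges carry the
#' boosting importance and supporting motif, drug edges link each drug to
#' its targets present in the network.
#'
#' @param network either a `grn_fit`, a data.frame of directed tf/target
#'   edges, or a data.frame of gene1/gene2 co-expression edges (with
#'   an optional `cor` or `weight` column).
#' @param drug_map a `drug_map` from [map_drugs] (optional).
#' @return a directed igraph; exportable via [write_graphml].
#' @export
build_combined_network <- function(network, drug_map = NULL) {
  if (inherits(network, "grn_fit")) network <- network$edges
  stopifnot(is.data.frame(network))
  if (all(c("tf", "target") %in% names(network))) {
    from <- network$tf; to <- network$target
    tfs <- unique(network$tf)
    edge_type <- rep("regulates", nrow(network))
    weight <- network$importance %||% rep(1, nrow(network))
    evidence <- network$motif_id %||% rep(NA_character_, nrow(network))
  } else if (all(c("gene1", "gene2") %in% names(network))) {
    from <- network$gene1; to <- network$gene2
    tfs <- character()
    edge_type <- rep("coexpression", nrow(network))
    weight <- network$cor %||% network$weight %||% rep(1, nrow(network))
    evidence <- rep(NA_character_, nrow(network))
  } else {
    stop("network must have tf/target or gene1/gene2 columns", call. = FALSE)
  }
  genes <- unique(c(from, to))
  nodes <- data.frame(name = genes,
                      node_type = ifelse(genes %in% tfs, "tf", "gene"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, edge_type = edge_type,
                      weight = as.numeric(weight), evidence = evidence,
                      stringsAsFactors = FALSE)
  if (!is.null(drug_map)) {
    stopifnot(inherits(drug_map, "drug_map"))
    assoc <- drug_map$associations
    assoc <- assoc[assoc$gene_symbol %in% genes, , drop = FALSE]
    if (nrow(assoc) > 0L) {
      drug_ids <- paste0("drug:", assoc$drug_id)
      dn <- unique(data.frame(name = drug_ids, node_type = "drug",
                              stringsAsFactors = FALSE))
      nodes <- rbind(nodes, dn)
      edges <- rbind(edges, data.frame(
        from = drug_ids, to = assoc$gene_symbol, edge_type = "drug_target",
        weight = 1, evidence = assoc$source, stringsAsFactors = FALSE))
    }
  }
  dangling <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(dangling) > 0L) {
    stop(sprintf("dangling edge endpoints: %s",
                 paste(head(dangling, 5L), collapse = ", ")), call. = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}
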