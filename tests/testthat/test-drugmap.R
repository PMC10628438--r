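toy_table <- function() {
  drug_table(data.frame(
    drug_id = c("A", "B", "C"), drug_name = c("a", "b", "c"),
    gene_symbol = c("g1", "g1", "g9"), action = "", source = "toy",
    stringsAsFactors = FALSE))
}

test_that("drug mapping is an exact symbol join with distinct-count summary", {
  dm <- map_drugs(c("g1", "g2"), toy_table())
  expect_equal(nrow(dm$associations), 2)
  expect_equal(dm$n_drugs, 2)
  expect_equal(dm$n_targeted_genes, 1)

  none <- map_drugs(c("x1", "x2"), toy_table())
  expect_equal(nrow(none$associations), 0)
  expect_equal(none$n_drugs, 0)
  expect_equal(none$n_targeted_genes, 0)
})

test_that("summary counts equal the distinct projections of the join", {
  set.seed(50)
  tab <- simulate_drug_table(sprintf("g%02d", 1:30), n_drugs = 15, seed = 3)
  dm <- map_drugs(sprintf("g%02d", 1:10), tab)
  expect_equal(dm$n_drugs, length(unique(dm$associations$drug_id)))
  expect_equal(dm$n_targeted_genes,
               length(unique(dm$associations$gene_symbol)))
})

test_that("records for genes outside the query never change the result", {
  base <- toy_table()
  extra <- drug_table(rbind(as.data.frame(base), data.frame(
    drug_id = "Z", drug_name = "z", gene_symbol = "unrelated",
    action = "", source = "toy")))
  a <- map_drugs(c("g1", "g2"), base)
  b <- map_drugs(c("g1", "g2"), extra)
  expect_equal(a$associations, b$associations)
  expect_equal(a$n_drugs, b$n_drugs)
})

test_that("empty and malformed tables are rejected", {
  empty <- drug_table(data.frame(drug_id = character(),
                                 drug_name = character(),
                                 gene_symbol = character(),
                                 action = character(), source = character()))
  expect_error(map_drugs("g1", empty), "empty")
  expect_error(drug_table(data.frame(drug_id = "", drug_name = "x",
                                     gene_symbol = "g1", action = "",
                                     source = "")), "empty drug_id")
  expect_error(drug_table(data.frame(drug_id = c("A", "A"),
                                     drug_name = "a",
                                     gene_symbol = c("g1", "g1"),
                                     action = "", source = "")),
               "duplicate")
})

test_that("packaged fixture yields exactly 20 drugs over 8 targeted genes", {
  tab <- read_drug_table(system.file("extdata", "synthetic_drug_table.tsv",
                                     package = "scgrnet"))
  genes <- read_tf_list(system.file("extdata", "synthetic_network_genes.txt",
                                    package = "scgrnet"))
  expect_equal(length(genes), 40)
  dm <- map_drugs(genes, tab)
  expect_equal(dm$n_drugs, 20)
  expect_equal(dm$n_targeted_genes, 8)
  expect_match(dm$provenance, "synthetic")
})

test_that("combined network typing and counts", {
  grn <- structure(list(edges = data.frame(
    tf = "TF1", target = c("g1", "g2"), importance = c(2, 1)),
    unannotated_tfs = character(), n_candidates = 2L), class = "grn_fit")
  tab <- drug_table(data.frame(drug_id = "D1", drug_name = "d",
                               gene_symbol = "g1", action = "", source = "s"))
  dm <- map_drugs(c("TF1", "g1", "g2"), tab)
  g <- build_combined_network(grn, dm)
  expect_equal(igraph::vcount(g), 4)   # TF1, g1, g2, drug:D1
  expect_equal(igraph::ecount(g), 3)
  types <- igraph::V(g)$node_type
  expect_equal(sort(types), c("drug", "gene", "gene", "tf"))
  expect_true("drug:D1" %in% igraph::V(g)$name)

  # without associations the graph is just the regulatory network
  g0 <- build_combined_network(grn, NULL)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 2)

  # co-expression edge lists also build, with undirected semantics recorded
  sub <- data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"),
                    cor = c(0.95, 0.91))
  gco <- build_combined_network(sub)
  expect_equal(unique(igraph::E(gco)$edge_type), "coexpression")
})
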