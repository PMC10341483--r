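edge_keys <- function(net) paste(net$edges$tf, net$edges$target)

test_that("loading edge lists unions files and merges duplicate edges", {
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tmode\tsource",
               "A\tB\tactivation\tdb1",
               "A\tC\tunknown\tdb1"), f1)
  writeLines(c("tf\ttarget\tmode\tsource",
               "A\tB\trepression\tdb2",
               "C\tD\tactivation\tdb2"), f2)
  net <- load_general_grn(c(f1, f2))
  expect_equal(nrow(net$edges), 3L)
  ab <- net$edges[net$edges$tf == "A" & net$edges$target == "B", ]
  expect_equal(ab$mode, "unknown")        # conflicting modes collapse
  expect_equal(ab$source, "db1,db2")      # sources concatenated
  expect_true(all(net$nodes$is_tf[net$nodes$gene_id %in% c("A", "C")]))
  expect_false(any(net$nodes$is_tf[net$nodes$gene_id %in% c("B", "D")]))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget", "A\tB", "\tC"), bad)
  expect_error(load_general_grn(bad), "malformed|empty")

  expect_equal(nrow(grn(NULL)$edges), 0L)
})

test_that("contextualize keeps exactly the edges of expressed TFs", {
  net <- grn(data.frame(tf = c("A", "A", "B", "C"),
                        target = c("B", "C", "D", "D"), stringsAsFactors = FALSE))
  all_tfs <- contextualize(net, c("A", "B", "C"))
  expect_equal(all_tfs$edges[, c("tf", "target")], net$edges[, c("tf", "target")])
  none <- contextualize(net, "Z")
  expect_equal(nrow(none$edges), 0L)
  expect_equal(nrow(none$nodes), 0L)
  some <- contextualize(net, c("B", "Z"))
  expect_equal(edge_keys(some), "B D")
  # isolated nodes dropped: A and C gone
  expect_equal(some$nodes$gene_id, c("B", "D"))
})

test_that("contextualize matches the literal filter oracle and is monotone", {
  set.seed(41)
  for (rep in 1:10) {
    e <- rand_edges(500, 40)
    net <- grn(e)
    ids <- unique(c(e$tf, e$target))
    expressed <- sample(ids, length(ids) %/% 3)
    got <- contextualize(net, expressed)
    exp <- oracle_contextualize(net$edges, expressed)
    expect_equal(got$edges[, c("tf", "target")],
                 exp[order(exp$tf, exp$target), c("tf", "target")],
                 ignore_attr = TRUE)
    # monotone in the expressed set
    bigger <- union(expressed, sample(ids, length(ids) %/% 3))
    got2 <- contextualize(net, bigger)
    expect_true(all(edge_keys(got) %in% edge_keys(got2)))
    # idempotent once the expressed set covers all retained TFs
    again <- contextualize(got, expressed)
    expect_equal(again$edges, got$edges)
  }
})

test_that("every retained edge source is a TF with out-degree >= 1", {
  set.seed(42)
  net <- grn(rand_edges(300, 30))
  ctx <- contextualize(net, sample(net$nodes$gene_id, 10))
  if (nrow(ctx$edges)) {
    outdeg <- table(ctx$edges$tf)
    expect_true(all(outdeg >= 1))
    expect_true(all(ctx$nodes$is_tf[ctx$nodes$gene_id %in% ctx$edges$tf]))
  }
})

test_that("annotation fills node statuses, leaves missing genes absent, idempotently", {
  net <- grn(data.frame(tf = "A", target = c("B", "C"), stringsAsFactors = FALSE))
  de <- data.frame(feature_id = c("B", "A"), status = c("down", "ns"),
                   stringsAsFactors = FALSE)
  prom <- data.frame(feature_id = "A", status = "up", stringsAsFactors = FALSE)
  flags <- data.frame(gene_id = c("B", "C"), cre_up = c(TRUE, FALSE),
                      cre_down = c(TRUE, FALSE), stringsAsFactors = FALSE)
  a1 <- annotate_network(net, de, prom, flags)
  n <- a1$nodes
  expect_equal(n$de_status[n$gene_id == "B"], "down")
  expect_equal(n$de_status[n$gene_id == "C"], "absent")
  expect_equal(n$promoter_acetyl[n$gene_id == "A"], "up")
  expect_equal(n$cre_acetyl[n$gene_id == "B"], "up")   # mixed flags: up precedence
  expect_equal(n$cre_acetyl[n$gene_id == "C"], "ns")
  a2 <- annotate_network(a1, de, prom, flags)
  expect_identical(a1$nodes, a2$nodes)
})

test_that("network comparison matches set algebra and reconstructs totals", {
  net_a <- grn(data.frame(tf = c("A", "A", "B"), target = c("B", "C", "C"),
                          stringsAsFactors = FALSE))
  expect_equal(unname(unlist(compare_networks(net_a, net_a)[, 4:6])), rep(0L, 6))
  empty <- grn(NULL)
  s <- compare_networks(net_a, empty)
  expect_equal(s$unique_nodes[1], s$total_nodes[1])
  expect_equal(s$unique_edges[1], s$total_edges[1])

  set.seed(43)
  for (rep in 1:10) {
    a <- grn(rand_edges(120, 25)); b <- grn(rand_edges(120, 25))
    got <- compare_networks(a, b)
    exp <- oracle_compare(a$nodes$gene_id, a$nodes$gene_id[a$nodes$is_tf], edge_keys(a),
                          b$nodes$gene_id, b$nodes$gene_id[b$nodes$is_tf], edge_keys(b))
    expect_equal(got$unique_nodes, unname(exp[c("unique_nodes_a", "unique_nodes_b")]))
    expect_equal(got$unique_tfs, unname(exp[c("unique_tfs_a", "unique_tfs_b")]))
    expect_equal(got$unique_edges, unname(exp[c("unique_edges_a", "unique_edges_b")]))
    # total = shared + unique, computed from the same union
    shared_nodes <- length(intersect(a$nodes$gene_id, b$nodes$gene_id))
    expect_equal(got$total_nodes, shared_nodes + got$unique_nodes)
  }
})

test_that("regulator subnetworks keep only out-edges of the chosen regulators", {
  net <- grn(data.frame(tf = c("R1", "R2", "R1", "X"),
                        target = c("T1", "T1", "T2", "T3"), stringsAsFactors = FALSE))
  sub <- cre_regulatory_subnetwork(net, c("R1", "R2"))
  expect_setequal(sub$nodes$gene_id, c("R1", "R2", "T1", "T2"))
  expect_equal(nrow(sub$edges), 3L)
  # shared target appears once, with in-edges from both regulators
  expect_equal(sum(sub$edges$target == "T1"), 2L)
  expect_equal(sum(sub$nodes$gene_id == "T1"), 1L)
  # regulator with no targets -> single node
  lone <- grn(data.frame(tf = "A", target = "B", stringsAsFactors = FALSE))
  solo <- cre_regulatory_subnetwork(lone, "B")
  expect_equal(solo$nodes$gene_id, "B")
  expect_equal(nrow(solo$edges), 0L)
  expect_warning(cre_regulatory_subnetwork(net, c("R1", "ZZ")), "skipped")

  set.seed(44)
  for (rep in 1:5) {
    e <- rand_edges(200, 30)
    net <- grn(e)
    regs <- sample(net$nodes$gene_id, 5)
    sub <- suppressWarnings(cre_regulatory_subnetwork(net, regs))
    exp <- e[e$tf %in% regs, , drop = FALSE]
    expect_setequal(edge_keys(sub), paste(exp$tf, exp$target))
  }
})

test_that("expressed-gene filter applies the normalized-mean threshold per condition", {
  k <- rbind(hi = c(100L, 110L, 90L, 100L, 100L, 110L),
             lo = c(1L, 2L, 1L, 40L, 50L, 45L),
             mid = c(30L, 35L, 28L, 31L, 29L, 33L))
  colnames(k) <- paste0("s", 1:6)
  cm <- count_matrix(k, rep(c("control", "mutant"), each = 3))
  expect_setequal(expressed_genes(cm, "control"), c("hi", "mid"))
  expect_setequal(expressed_genes(cm, "mutant"), c("hi", "mid", "lo"))
  expect_error(expressed_genes(cm, time = "9wk", condition = NULL), NA)
})

test_that("GraphML export writes node attributes readable by igraph", {
  net <- grn(data.frame(tf = "A", target = "B", stringsAsFactors = FALSE))
  net <- annotate_network(net, de = data.frame(feature_id = "B", status = "down",
                                               stringsAsFactors = FALSE))
  p <- tempfile(fileext = ".graphml")
  write_graphml(net, p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::V(g)$de_status[igraph::V(g)$name == "B"], "down")
  expect_equal(igraph::ecount(g), 1)
})
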