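#' Physical-interaction set
#'
#' Unordered gene pairs with symmetric lookup; self-pairs are rejected.
#'
#' @param pairs `data.frame` with two character columns (`a`, `b`).
#' @return A list of class `ppi_set`.
#' @export
ppi_set <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(a = as.character(pairs[[1]]), b = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
    if (any(pairs$a == pairs$b)) stop("self-pairs are not allowed in a physical-interaction set")
    lo <- pmin(pairs$a, pairs$b); hi <- pmax(pairs$a, pairs$b)
    pairs <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs), class = "ppi_set")
}

#' Read physical-interaction pairs from a TSV
#'
#' @param path two-column TSV (header optional: `a`, `b`).
#' @return A [ppi_set()].
#' @export
read_ppi <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^a\t", first)
  tab <- read.table(path, header = header, sep = "\t", stringsAsFactors = FALSE)
  ppi_set(tab)
}

ppi_partners <- function(ppi, id, within) {
  p <- ppi$pairs
  hit <- c(p$b[p$a == id], p$a[p$b == id])
  sort(intersect(hit, within))
}

#' Upstream regulatory neighborhood of a gene set
#'
#' Walks regulatory edges in reverse from the seed genes, collecting
#' regulators up to `depth` steps upstream, and returns the subgraph induced
#' by the collected node set (all edges of the network among those nodes).
#' Seed genes absent from the network are skipped with a message; an empty
#' intersection is an error.
#'
#' @param network a [grn()].
#' @param de_genes character vector of seed (differentially expressed) genes.
#' @param depth number of upstream steps (default 2).
#' @return A [grn()] induced on the neighborhood, with attribute
#'   `"seed_genes"` holding the seeds used.
#' @export
upstream_neighborhood <- function(network, de_genes, depth = 2L) {
  stopifnot(depth >= 1)
  seeds <- intersect(de_genes, network$nodes$gene_id)
  missing <- setdiff(de_genes, seeds)
  if (length(missing))
    message(length(missing), " seed gene(s) absent from the network, skipped")
  if (length(seeds) == 0) stop("no seed gene is present in the network")
  nodes <- frontier <- seeds
  for (i in seq_len(depth)) {
    regs <- network$edges$tf[network$edges$target %in% frontier]
    frontier <- setdiff(regs, nodes)
    nodes <- union(nodes, frontier)
    if (length(frontier) == 0) break
  }
  keep <- network$edges$tf %in% nodes & network$edges$target %in% nodes
  out <- grn(network$edges[keep, , drop = FALSE])
  iso <- setdiff(nodes, out$nodes$gene_id)
  if (length(iso)) {
    out$nodes <- rbind(out$nodes,
                       data.frame(gene_id = iso, is_tf = FALSE, de_status = "absent",
                                  promoter_acetyl = "absent", cre_acetyl = "absent",
                                  stringsAsFactors = FALSE))
    out$nodes <- out$nodes[order(out$nodes$gene_id), , drop = FALSE]
    rownames(out$nodes) <- NULL
  }
  out <- carry_node_attrs(out, network)
  attr(out, "seed_genes") <- sort(seeds)
  out
}

#' Densest core by iterative minimal-out-degree deletion
#'
#' Operating on the largest weakly connected component of the subnetwork,
#' repeatedly picks the node with minimal current out-degree (ties: minimal
#' in-degree, then lexicographic gene id) and tentatively deletes it. If the
#' remainder is weakly connected and still has at least `min_core_size`
#' nodes, the deletion is committed and degrees are recomputed; if the
#' deletion would disconnect the remainder (two or more weak components,
#' isolated nodes included) or shrink it below `min_core_size`, the process
#' stops without committing. The survivors are the core.
#'
#' @param subnetwork a [grn()] (typically from [upstream_neighborhood()]).
#' @param min_core_size stop before shrinking below this many nodes
#'   (default 2, preventing degenerate single-node cores).
#' @return A list with `core` (character vector of surviving gene ids, sorted)
#'   and `trace` (`data.frame` of committed deletions in order: `node`,
#'   `out_degree`, `in_degree`).
#' @export
densest_core <- function(subnetwork, min_core_size = 2L) {
  stopifnot(nrow(subnetwork$nodes) > 0)
  g <- igraph::graph_from_data_frame(subnetwork$edges[, c("tf", "target")],
                                     directed = TRUE,
                                     vertices = subnetwork$nodes["gene_id"])
  comp <- igraph::components(g, mode = "weak")
  biggest <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  trace <- list()
  repeat {
    n <- igraph::vcount(g)
    if (n <= min_core_size) break
    outd <- igraph::degree(g, mode = "out")
    ind <- igraph::degree(g, mode = "in")
    nm <- igraph::V(g)$name
    o <- order(outd, ind, nm)
    cand <- o[1]
    g2 <- igraph::delete_vertices(g, cand)
    if (igraph::vcount(g2) == 0 || igraph::components(g2, mode = "weak")$no > 1)
      break
    trace[[length(trace) + 1]] <- data.frame(node = nm[cand],
                                             out_degree = unname(outd[cand]),
                                             in_degree = unname(ind[cand]),
                                             stringsAsFactors = FALSE)
    g <- g2
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(node = character(), out_degree = integer(), in_degree = integer(),
               stringsAsFactors = FALSE)
  list(core = sort(igraph::V(g)$name), trace = trace)
}

#' Validate master-regulator candidates
#'
#' Candidates are the surviving core nodes that are TFs in the supplied
#' network. For each candidate the evidence is (a) the candidates with a
#' regulatory edge into it and (b) the candidates paired with it in the
#' physical-interaction set. Under `rule = "both"` (default) a candidate is a
#' validated master regulator iff both evidence sets are non-empty; `"either"`
#' requires one; `"regulation_only"` ignores physical interactions.
#'
#' @param candidates character vector (e.g. `core` from [densest_core()]).
#' @param network a [grn()] whose edges define regulation among candidates
#'   and whose `is_tf` flags define TF status.
#' @param ppi a [ppi_set()].
#' @param rule `"both"`, `"either"` or `"regulation_only"`.
#' @param trace optional deletion trace to embed in the report.
#' @param seed_genes optional seed-gene set to embed in the report.
#' @return A list of class `mr_report`: `seed_genes`, `neighborhood_nodes`,
#'   `core_candidates`, `deletion_trace`, `validated_mrs` and `evidence`
#'   (per-candidate `data.frame`).
#' @export
validate_mrs <- function(candidates, network, ppi,
                         rule = c("both", "either", "regulation_only"),
                         trace = NULL, seed_genes = character()) {
  rule <- match.arg(rule)
  stopifnot(all(candidates %in% network$nodes$gene_id))
  tfs <- network$nodes$gene_id[network$nodes$is_tf]
  cand <- sort(intersect(candidates, tfs))
  ev <- lapply(cand, function(id) {
    reg <- sort(unique(network$edges$tf[network$edges$target == id &
                                          network$edges$tf %in% cand &
                                          network$edges$tf != id]))
    phys <- ppi_partners(ppi, id, setdiff(cand, id))
    ok <- switch(rule,
                 both = length(reg) > 0 && length(phys) > 0,
                 either = length(reg) > 0 || length(phys) > 0,
                 regulation_only = length(reg) > 0)
    data.frame(candidate = id,
               regulated_by_candidates = paste(reg, collapse = ","),
               physical_partners_in_candidates = paste(phys, collapse = ","),
               validated = ok, stringsAsFactors = FALSE)
  })
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(candidate = character(), regulated_by_candidates = character(),
               physical_partners_in_candidates = character(), validated = logical(),
               stringsAsFactors = FALSE)
  structure(list(seed_genes = sort(seed_genes),
                 neighborhood_nodes = sort(network$nodes$gene_id),
                 core_candidates = cand,
                 deletion_trace = trace,
                 validated_mrs = ev$candidate[ev$validated],
                 evidence = ev),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("mr_report:", length(x$core_candidates), "candidates,",
      length(x$validated_mrs), "validated master regulators\n")
  if (length(x$validated_mrs))
    cat("  validated:", paste(x$validated_mrs, collapse = ", "), "\n")
  invisible(x)
}

#' Contrast master regulators across conditions
#'
#' Set algebra on the validated MR sets of two reports.
#'
#' @param report_control,report_mutant [validate_mrs()] reports.
#' @return A list with `shared`, `control_only` and `mutant_only` (sorted
#'   character vectors, pairwise disjoint).
#' @export
mr_condition_contrast <- function(report_control, report_mutant) {
  a <- report_control$validated_mrs
  b <- report_mutant$validated_mrs
  list(shared = sort(intersect(a, b)),
       control_only = sort(setdiff(a, b)),
       mutant_only = sort(setdiff(b, a)))
}

#' Write an MR report and its deletion trace as TSV files
#'
#' @param report an `mr_report`.
#' @param path output path for the per-candidate evidence table.
#' @param trace_path optional output path for the deletion trace.
#' @return `path`, invisibly.
#' @export
write_mr_report <- function(report, path, trace_path = NULL) {
  write.table(report$evidence, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace_path) && !is.null(report$deletion_trace))
    write.table(report$deletion_trace, trace_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
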