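#' Construct a directed regulatory network
#'
#' A regulatory network holds directed TF-to-target edges plus a node table
#' with regulatory and molecular-state attributes (`is_tf`, `de_status`,
#' `promoter_acetyl`, `cre_acetyl`, each of `up`/`down`/`ns`/`absent`).
#' Duplicate (tf, target) pairs are merged: sources are concatenated and
#' conflicting modes collapse to `unknown`. Any node with outgoing edges is
#' flagged as a TF.
#'
#' @param edges `data.frame` with columns `tf`, `target` and optional `mode`
#'   (`activation`/`repression`/`unknown`) and `source`.
#' @return A list of class `grn` with elements `edges` and `nodes`.
#' @export
grn <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(tf = character(), target = character(), mode = character(),
                        source = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(tf = as.character(edges$tf), target = as.character(edges$target),
                        mode = if (!is.null(edges$mode)) as.character(edges$mode) else "unknown",
                        source = if (!is.null(edges$source)) as.character(edges$source) else "unknown",
                        stringsAsFactors = FALSE)
    if (anyNA(edges$tf) || anyNA(edges$target) || any(edges$tf == "") || any(edges$target == ""))
      stop("malformed edge rows: empty tf/target")
    key <- paste(edges$tf, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      mode <- tapply(edges$mode, key, function(m) {
        u <- unique(m[m != "unknown"])
        if (length(u) == 1) u else "unknown"
      })
      src <- tapply(edges$source, key, function(s) paste(sort(unique(s)), collapse = ","))
      first <- !duplicated(key)
      edges <- edges[first, , drop = FALSE]
      k <- paste(edges$tf, edges$target, sep = "\r")
      edges$mode <- unname(mode[k])
      edges$source <- unname(src[k])
    }
    edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  ids <- sort(unique(c(edges$tf, edges$target)))
  nodes <- data.frame(gene_id = ids, is_tf = ids %in% edges$tf,
                      de_status = rep("absent", length(ids)),
                      promoter_acetyl = rep("absent", length(ids)),
                      cre_acetyl = rep("absent", length(ids)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$nodes), "nodes (", sum(x$nodes$is_tf), "TFs ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Load and union general regulatory networks from edge-list files
#'
#' Each file is a TSV with columns `tf`, `target` and optionally `mode` and
#' `source` (header optional when exactly in that order). The union of the
#' edge sets is returned; duplicate pairs across files are merged as in
#' [grn()].
#'
#' @param paths one or more edge-list file paths.
#' @return A [grn()].
#' @export
load_general_grn <- function(paths) {
  parts <- lapply(paths, function(p) {
    first <- readLines(p, n = 1L)
    header <- grepl("^tf\t", first)
    args <- list(p, header = header, sep = "\t", stringsAsFactors = FALSE,
                 fill = FALSE)
    if (!header)
      args$col.names <- c("tf", "target", "mode", "source")[
        seq_along(strsplit(first, "\t", fixed = TRUE)[[1]])]
    tab <- tryCatch(
      do.call(read.table, args),
      error = function(e) stop("malformed edge list '", p, "': ",
                               conditionMessage(e), call. = FALSE))
    if (!all(c("tf", "target") %in% names(tab)))
      stop("edge list '", p, "' lacks tf/target columns")
    bad <- which(is.na(tab$tf) | is.na(tab$target) | tab$tf == "" | tab$target == "")
    if (length(bad))
      stop("malformed edge list '", p, "': empty tf/target at data line ", bad[1])
    if (is.null(tab$source)) tab$source <- basename(p)
    tab
  })
  all_edges <- do.call(rbind, lapply(parts, function(t)
    t[, intersect(c("tf", "target", "mode", "source"), names(t)), drop = FALSE]))
  grn(all_edges)
}

#' Write a network as an edge-list TSV
#'
#' @param network a [grn()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a network to an igraph object (attributes attached)
#'
#' @param network a [grn()].
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("tf", "target")],
                                     directed = TRUE, vertices = network$nodes)
  igraph::set_edge_attr(g, "mode", value = network$edges$mode)
}

#' Export a network with attributes to GraphML
#'
#' @param network a [grn()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Genes called expressed from a count matrix
#'
#' A gene is expressed in a condition when its mean normalized count across
#' that condition's samples reaches `threshold`. This is the filter used to
#' contextualize the general network.
#'
#' @param cm a [count_matrix()].
#' @param condition which condition's samples to average (`"control"` or
#'   `"mutant"`); `NULL` averages all samples.
#' @param time optional time label to additionally subset samples.
#' @param threshold mean normalized count cutoff (default 10).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(cm, condition = NULL, time = NULL, threshold = 10) {
  sf <- size_factors(cm)
  q <- sweep(cm$counts, 2, sf, `/`)
  keep <- rep(TRUE, ncol(q))
  if (!is.null(condition)) keep <- keep & cm$condition == condition
  if (!is.null(time) && !is.null(cm$time)) keep <- keep & cm$time == time
  if (!any(keep)) stop("no samples match the requested condition/time")
  rownames(q)[rowMeans(q[, keep, drop = FALSE]) >= threshold]
}

#' Contextualize a general network by expressed TFs
#'
#' Retains an edge (tf, target) if and only if the TF is expressed; the node
#' set becomes the endpoints of retained edges (isolated nodes are dropped).
#' Node attributes of surviving nodes are preserved.
#'
#' @param general a [grn()].
#' @param expressed character vector of expressed gene ids.
#' @return A contextualized [grn()].
#' @export
contextualize <- function(general, expressed) {
  stopifnot(length(expressed) > 0)
  keep <- general$edges$tf %in% expressed
  edges <- general$edges[keep, , drop = FALSE]
  out <- grn(edges)
  carry_node_attrs(out, general)
}

carry_node_attrs <- function(network, from) {
  i <- match(network$nodes$gene_id, from$nodes$gene_id)
  for (col in c("de_status", "promoter_acetyl", "cre_acetyl")) {
    v <- from$nodes[[col]][i]
    network$nodes[[col]] <- ifelse(is.na(v), "absent", v)
  }
  network
}

#' Attach expression and acetylation status to network nodes
#'
#' Fills `de_status` from a gene-level differential expression table,
#' `promoter_acetyl` from a promoter-level differential acetylation table
#' (keyed by gene id), and `cre_acetyl` from the per-gene CRE flags of
#' [cre_acetylation_table()]. Genes absent from a table keep status `absent`.
#' A gene with both up- and down-acetylated CRE regions is labelled `up`
#' here (single-field precedence); both flags remain available in the CRE
#' table itself. The operation is idempotent.
#'
#' @param network a [grn()].
#' @param de gene-level [nb_test()] result, or `NULL`.
#' @param prom_acetyl promoter-level [nb_test()] result keyed by gene id, or
#'   `NULL`.
#' @param cre_flags `gene_flags` from [cre_acetylation_table()], or `NULL`.
#' @return The network with node attributes filled.
#' @export
annotate_network <- function(network, de = NULL, prom_acetyl = NULL, cre_flags = NULL) {
  nodes <- network$nodes
  fill <- function(current, tab) {
    s <- setNames(tab$status, tab$feature_id)[nodes$gene_id]
    ifelse(is.na(s), "absent", unname(s))
  }
  if (!is.null(de)) nodes$de_status <- fill(nodes$de_status, de)
  if (!is.null(prom_acetyl)) nodes$promoter_acetyl <- fill(nodes$promoter_acetyl, prom_acetyl)
  if (!is.null(cre_flags)) {
    i <- match(nodes$gene_id, cre_flags$gene_id)
    up <- !is.na(i) & cre_flags$cre_up[pmax(i, 1L)]
    down <- !is.na(i) & cre_flags$cre_down[pmax(i, 1L)]
    nodes$cre_acetyl <- ifelse(is.na(i), "absent",
                               ifelse(up & down, "up",
                                      ifelse(up, "up", ifelse(down, "down", "ns"))))
  }
  network$nodes <- nodes
  network
}

#' Compare two networks (totals and unique elements)
#'
#' Totals per network plus counts of nodes, TFs and edges present in one
#' network and not in the other, in the bookkeeping style of condition-level
#' network summaries.
#'
#' @param a,b [grn()] objects in the same identifier namespace.
#' @param names labels for the two networks.
#' @return `data.frame` with one row per network and columns `total_nodes`,
#'   `total_tfs`, `total_edges`, `unique_nodes`, `unique_tfs`, `unique_edges`.
#' @export
compare_networks <- function(a, b, names = c("a", "b")) {
  ek <- function(n) paste(n$edges$tf, n$edges$target, sep = "\r")
  tf <- function(n) n$nodes$gene_id[n$nodes$is_tf]
  row <- function(x, y) data.frame(
    total_nodes = nrow(x$nodes), total_tfs = sum(x$nodes$is_tf),
    total_edges = nrow(x$edges),
    unique_nodes = length(setdiff(x$nodes$gene_id, y$nodes$gene_id)),
    unique_tfs = length(setdiff(tf(x), tf(y))),
    unique_edges = length(setdiff(ek(x), ek(y))))
  out <- rbind(row(a, b), row(b, a))
  rownames(out) <- names
  out
}

#' Induced subnetwork of chosen regulators and their direct targets
#'
#' Returns the subnetwork on `regulator_ids` plus their direct targets,
#' retaining only edges going out of `regulator_ids`. Unknown regulator ids
#' are skipped with a warning. Regulators with no targets remain as isolated
#' nodes.
#'
#' @param network a [grn()].
#' @param regulator_ids character vector of regulator gene ids.
#' @return A [grn()] (node attributes preserved; isolated regulators kept).
#' @export
cre_regulatory_subnetwork <- function(network, regulator_ids) {
  unknown <- setdiff(regulator_ids, network$nodes$gene_id)
  if (length(unknown)) {
    warning("regulator id(s) not in network, skipped: ", paste(unknown, collapse = ", "))
    regulator_ids <- setdiff(regulator_ids, unknown)
  }
  edges <- network$edges[network$edges$tf %in% regulator_ids, , drop = FALSE]
  out <- grn(edges)
  # keep regulators without targets as isolated nodes
  iso <- setdiff(regulator_ids, out$nodes$gene_id)
  if (length(iso)) {
    out$nodes <- rbind(out$nodes,
                       data.frame(gene_id = iso, is_tf = FALSE, de_status = "absent",
                                  promoter_acetyl = "absent", cre_acetyl = "absent",
                                  stringsAsFactors = FALSE))
    out$nodes <- out$nodes[order(out$nodes$gene_id), , drop = FALSE]
    rownames(out$nodes) <- NULL
  }
  carry_node_attrs(out, network)
}
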