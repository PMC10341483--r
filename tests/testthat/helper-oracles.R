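# Independently coded brute-force oracles. These deliberately avoid the
# package's overlap/graph machinery: plain loops, literal definitions.

oracle_intersect <- function(a, b, min_overlap = 1L) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
        if (ov >= min_overlap) { keep[i] <- TRUE; break }
      }
    }
  }
  out <- unique(a[keep, c("chrom", "start", "end"), drop = FALSE])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_tss <- function(ann) {
  ifelse(ann$strand == "+", ann$start, ann$end - 1L)
}

oracle_assign <- function(motifs, ann, max_distance = 3000L) {
  tss <- oracle_tss(ann)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    mid <- floor((motifs$start[i] + motifs$end[i]) / 2)
    for (j in seq_len(nrow(ann))) {
      if (motifs$chrom[i] == ann$chrom[j] && abs(mid - tss[j]) <= max_distance) {
        rows[[length(rows) + 1]] <- data.frame(
          motif_id = motifs$name[i], gene_id = ann$gene_id[j],
          distance = abs(mid - tss[j]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(motif_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$motif_id, out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_classify <- function(regions, ann, windows, extent = 1000L) {
  tss <- setNames(oracle_tss(ann), ann$gene_id)
  best <- function(cands, mid) {
    if (!length(cands)) return(NA_character_)
    d <- abs(mid - unname(tss[cands]))
    cands[order(d, cands)][1]
  }
  n <- nrow(regions)
  loc <- character(n); gid <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    pw <- windows$gene_id[windows$chrom == regions$chrom[i] &
                            windows$start <= mid & mid < windows$end]
    gb <- ann$gene_id[ann$chrom == regions$chrom[i] &
                        ann$start <= mid & mid < ann$end]
    ds <- character()
    for (j in seq_len(nrow(ann))) {
      if (ann$chrom[j] != regions$chrom[i]) next
      hit <- if (ann$strand[j] == "+")
        mid >= ann$end[j] && mid < ann$end[j] + extent
      else
        mid >= ann$start[j] - extent && mid < ann$start[j]
      if (hit) ds <- c(ds, ann$gene_id[j])
    }
    if (length(pw)) { loc[i] <- "promoter"; gid[i] <- best(pw, mid) }
    else if (length(gb)) { loc[i] <- "gene_body"; gid[i] <- best(gb, mid) }
    else if (length(ds)) { loc[i] <- "downstream"; gid[i] <- best(ds, mid) }
    else loc[i] <- "intergenic"
  }
  data.frame(location = loc, gene_id = gid, stringsAsFactors = FALSE)
}

# reverse-BFS reachability truncated at depth, then induced edges
oracle_upstream <- function(edges, seeds, depth) {
  nodes <- seeds
  frontier <- seeds
  for (d in seq_len(depth)) {
    regs <- character()
    for (i in seq_len(nrow(edges)))
      if (edges$target[i] %in% frontier) regs <- c(regs, edges$tf[i])
    frontier <- setdiff(unique(regs), nodes)
    nodes <- union(nodes, frontier)
  }
  keep <- edges$tf %in% nodes & edges$target %in% nodes
  list(nodes = sort(nodes), edges = edges[keep, c("tf", "target"), drop = FALSE])
}

oracle_contextualize <- function(edges, expressed) {
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) keep[i] <- edges$tf[i] %in% expressed
  edges[keep, , drop = FALSE]
}

oracle_compare <- function(a_nodes, a_tfs, a_edgekeys, b_nodes, b_tfs, b_edgekeys) {
  c(unique_nodes_a = sum(!a_nodes %in% b_nodes),
    unique_tfs_a = sum(!a_tfs %in% b_tfs),
    unique_edges_a = sum(!a_edgekeys %in% b_edgekeys),
    unique_nodes_b = sum(!b_nodes %in% a_nodes),
    unique_tfs_b = sum(!b_tfs %in% a_tfs),
    unique_edges_b = sum(!b_edgekeys %in% a_edgekeys))
}

# literal simulation of the pruning rule, with hand-coded weak-connectivity
oracle_weakly_connected <- function(nodes, edges) {
  if (length(nodes) <= 1) return(TRUE)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$tf[i]; b <- edges$target[i]
    if (a %in% nodes && b %in% nodes) {
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- nodes[1]; queue <- nodes[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(adj[[v]], seen)
    seen <- c(seen, nxt); queue <- c(queue, nxt)
  }
  length(seen) == length(nodes)
}

oracle_densest_core <- function(nodes, edges, min_core_size = 2L) {
  # restrict to the largest weakly connected component
  comps <- list()
  left <- nodes
  while (length(left)) {
    seen <- left[1]; queue <- left[1]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- union(edges$target[edges$tf == v], edges$tf[edges$target == v])
      nxt <- setdiff(intersect(nb, left), seen)
      seen <- c(seen, nxt); queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1]] <- seen
    left <- setdiff(left, seen)
  }
  sizes <- lengths(comps)
  cur <- sort(comps[[which.max(sizes)]])
  trace <- character()
  repeat {
    if (length(cur) <= min_core_size) break
    e <- edges[edges$tf %in% cur & edges$target %in% cur, , drop = FALSE]
    outd <- vapply(cur, function(v) sum(e$tf == v), integer(1))
    ind <- vapply(cur, function(v) sum(e$target == v), integer(1))
    pick <- cur[order(outd, ind, cur)][1]
    rest <- setdiff(cur, pick)
    e2 <- e[e$tf != pick & e$target != pick, , drop = FALSE]
    if (length(rest) == 0 || !oracle_weakly_connected(rest, e2)) break
    trace <- c(trace, pick)
    cur <- rest
  }
  list(core = sort(cur), trace = trace)
}

oracle_validate <- function(candidates, edges, ppi_pairs, tfs, rule = "both") {
  cand <- sort(intersect(candidates, tfs))
  ok <- vapply(cand, function(id) {
    reg <- any(edges$target == id & edges$tf %in% setdiff(cand, id))
    phys <- any((ppi_pairs$a == id & ppi_pairs$b %in% setdiff(cand, id)) |
                  (ppi_pairs$b == id & ppi_pairs$a %in% setdiff(cand, id)))
    switch(rule, both = reg && phys, either = reg || phys, regulation_only = reg)
  }, logical(1))
  cand[ok]
}

# literal definition of median-of-ratios with geometric-mean reference
oracle_size_factors <- function(k) {
  geo <- apply(k, 1, function(x) prod(x)^(1 / length(x)))
  usable <- apply(k, 1, function(x) all(x > 0))
  apply(k, 2, function(col) median((col / geo)[usable]))
}

# --- random-instance generators -------------------------------------------

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                           max_len = 60L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_annotation <- function(n_genes, chroms = c("chr1", "chr2"), span = 100000L) {
  start <- sample.int(span, n_genes, replace = TRUE)
  gene_annotation(gene_id = sprintf("g%03d", seq_len(n_genes)),
                  chrom = sample(chroms, n_genes, replace = TRUE),
                  start = start, end = start + sample(500:3000, n_genes, replace = TRUE),
                  strand = sample(c("+", "-"), n_genes, replace = TRUE))
}

rand_edges <- function(n_edges, n_nodes = 30L) {
  ids <- sprintf("n%03d", seq_len(n_nodes))
  e <- unique(data.frame(tf = sample(ids, n_edges, replace = TRUE),
                         target = sample(ids, n_edges, replace = TRUE),
                         stringsAsFactors = FALSE))
  e[e$tf != e$target, , drop = FALSE]
}
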