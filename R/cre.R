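#' Assign motif occurrences to putative regulated genes by TSS distance
#'
#' A motif occurrence is assigned to every gene on the same chromosome whose
#' TSS lies within `max_distance` bp of the motif midpoint
#' (`floor((start + end) / 2)`, 0-based). One assignment row is produced per
#' (motif, gene) pair; motifs with no gene in range produce none. With
#' `nearest_only = TRUE` only the nearest TSS is kept (ties: lexicographic
#' gene id).
#'
#' @param motifs `data.frame` of motif occurrences with columns `chrom`,
#'   `start`, `end`, `name` (motif id) and optionally `score`, `strand`
#'   (0-based half-open; strand is carried but ignored).
#' @param ann a [gene_annotation()].
#' @param max_distance assignment threshold in bp (default 3000, the +/-3 kb
#'   rule).
#' @param nearest_only keep only the nearest gene per motif.
#' @return `data.frame` with columns `motif_id`, `chrom`, `midpoint`,
#'   `gene_id`, `distance`.
#' @export
assign_cre_genes <- function(motifs, ann, max_distance = 3000L, nearest_only = FALSE) {
  stopifnot(nrow(ann) > 0)
  empty <- data.frame(motif_id = character(), chrom = character(),
                      midpoint = integer(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (nrow(motifs) == 0) return(empty)
  mid <- as.integer(floor((motifs$start + motifs$end) / 2))
  tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  # genes reachable from a motif midpoint = TSS windows of +/- max_distance
  # hit by the midpoint (1-bp) position
  gp <- granges_pair(motifs$chrom, mid, mid + 1L,
                     ann$chrom, pmax(tss - max_distance, 0L), tss + max_distance + 1L)
  hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
  qi <- queryHits(hits); si <- subjectHits(hits)
  dist <- abs(mid[qi] - tss[si])
  keep <- dist <= max_distance
  qi <- qi[keep]; si <- si[keep]; dist <- dist[keep]
  out <- data.frame(motif_id = if (!is.null(motifs$name)) motifs$name[qi] else
                      paste0("motif_", qi),
                    chrom = motifs$chrom[qi], midpoint = mid[qi],
                    gene_id = ann$gene_id[si], distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$motif_id, out$distance, out$gene_id), , drop = FALSE]
  if (nearest_only && nrow(out))
    out <- out[!duplicated(out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a region's genomic location relative to genes
#'
#' Each region is labelled by its midpoint with precedence
#' promoter > gene body > downstream > intergenic: `promoter` if the midpoint
#' falls in any promoter window, else `gene_body` if inside any gene
#' `[start, end)`, else `downstream` if within `downstream_extent` bp past a
#' gene's 3' end (strand-aware: beyond `end` for `+` genes, before `start`
#' for `-` genes), else `intergenic`. The matched gene is reported; ties are
#' broken by nearest TSS, then lexicographic gene id.
#'
#' @param regions interval `data.frame` (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param ann a [gene_annotation()].
#' @param windows promoter windows from [build_promoter_windows()] on `ann`.
#' @param downstream_extent bp past the 3' end counted as downstream
#'   (default 1000).
#' @return `data.frame` with columns `region_id`, `chrom`, `midpoint`,
#'   `location`, `gene_id` (`NA` for intergenic).
#' @export
classify_location <- function(regions, ann, windows, downstream_extent = 1000L) {
  n <- nrow(regions)
  mid <- as.integer(floor((regions$start + regions$end) / 2))
  ids <- if (!is.null(regions$name)) regions$name else paste0("region_", seq_len(n))
  tss <- setNames(ifelse(ann$strand == "+", ann$start, ann$end - 1L), ann$gene_id)
  lev <- unique(c(regions$chrom, ann$chrom, windows$chrom))
  gmid <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                                 IRanges::IRanges(mid + 1L, mid + 1L))

  pick <- function(hits, gene_ids, midpt) {
    # per query, the gene with nearest TSS then lexicographic id
    if (length(hits) == 0) return(rep(NA_character_, n))
    qi <- queryHits(hits)
    gid <- gene_ids[subjectHits(hits)]
    d <- abs(midpt[qi] - unname(tss[gid]))
    o <- order(qi, d, gid)
    qi <- qi[o]; gid <- gid[o]
    res <- rep(NA_character_, n)
    first <- !duplicated(qi)
    res[qi[first]] <- gid[first]
    res
  }

  gprom <- GenomicRanges::GRanges(factor(windows$chrom, levels = lev),
                                  IRanges::IRanges(windows$start + 1L, windows$end))
  prom_gene <- pick(GenomicRanges::findOverlaps(gmid, gprom), windows$gene_id, mid)

  gbody <- GenomicRanges::GRanges(factor(ann$chrom, levels = lev),
                                  IRanges::IRanges(ann$start + 1L, ann$end))
  body_gene <- pick(GenomicRanges::findOverlaps(gmid, gbody), ann$gene_id, mid)

  ds_start <- ifelse(ann$strand == "+", ann$end, pmax(ann$start - downstream_extent, 0L))
  ds_end <- ifelse(ann$strand == "+", ann$end + downstream_extent, ann$start)
  ok <- ds_start < ds_end
  gds <- GenomicRanges::GRanges(factor(ann$chrom[ok], levels = lev),
                                IRanges::IRanges(ds_start[ok] + 1L, ds_end[ok]))
  ds_gene <- pick(GenomicRanges::findOverlaps(gmid, gds), ann$gene_id[ok], mid)

  location <- ifelse(!is.na(prom_gene), "promoter",
                     ifelse(!is.na(body_gene), "gene_body",
                            ifelse(!is.na(ds_gene), "downstream", "intergenic")))
  gene_id <- ifelse(!is.na(prom_gene), prom_gene,
                    ifelse(!is.na(body_gene), body_gene, ds_gene))
  data.frame(region_id = ids, chrom = regions$chrom, midpoint = mid,
             location = location, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Merge CRE assignments with their differential-acetylation results
#'
#' One row per (motif, gene) assignment, carrying the acetylation status of
#' the CRE region (matched to `diff$feature_id` by motif id; unmatched ids are
#' reported with a warning and status `absent`, never dropped) plus the
#' region's location label. A per-gene flag table marks genes reachable from
#' at least one differentially acetylated CRE; a gene hit by both an up- and a
#' down-acetylated region keeps both flags.
#'
#' @param assignments output of [assign_cre_genes()].
#' @param diff a [nb_test()]-style result keyed by CRE region / motif id.
#' @param locations optional output of [classify_location()] keyed by the same
#'   region ids.
#' @return A list with `table` (per-assignment rows: `motif_id`, `gene_id`,
#'   `distance`, `location`, `acetyl_status`) and `gene_flags` (`gene_id`,
#'   `cre_up`, `cre_down`).
#' @export
cre_acetylation_table <- function(assignments, diff, locations = NULL) {
  status <- setNames(diff$status, diff$feature_id)
  st <- unname(status[assignments$motif_id])
  unmatched <- unique(assignments$motif_id[is.na(st)])
  if (length(unmatched))
    warning(length(unmatched), " assigned region id(s) absent from the ",
            "differential table: ", paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  st[is.na(st)] <- "absent"
  loc <- rep(NA_character_, nrow(assignments))
  if (!is.null(locations))
    loc <- unname(setNames(locations$location, locations$region_id)[assignments$motif_id])
  tab <- data.frame(motif_id = assignments$motif_id, gene_id = assignments$gene_id,
                    distance = assignments$distance, location = loc,
                    acetyl_status = st, stringsAsFactors = FALSE)
  genes <- unique(tab$gene_id)
  gene_flags <- data.frame(
    gene_id = genes,
    cre_up = vapply(genes, function(g) any(tab$acetyl_status[tab$gene_id == g] == "up"), logical(1)),
    cre_down = vapply(genes, function(g) any(tab$acetyl_status[tab$gene_id == g] == "down"), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, gene_flags = gene_flags)
}
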