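#' @importFrom GenomicRanges GRanges findOverlaps seqnames strand
#' @importFrom IRanges IRanges pintersect
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom stats median p.adjust pnorm rnbinom rnorm runif rpois setNames
#' @importFrom utils read.table write.table
NULL

# All interval objects in this package use 0-based half-open coordinates
# (BED convention). GTF and GRanges conversions happen only at the I/O and
# overlap-engine boundaries.

#' Construct a gene annotation table
#'
#' A gene annotation is a `data.frame` with one row per gene and columns
#' `gene_id`, `chrom`, `start`, `end` (0-based half-open) and `strand`
#' (`"+"` or `"-"`). The transcription start site (TSS) is derived from the
#' strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`0 <= start < end`).
#' @param strand character vector, each `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  ann <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand), stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (nrow(ann)) {
    if (anyDuplicated(ann$gene_id))
      stop("duplicate gene_id in annotation: ",
           paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
    if (any(ann$start < 0)) stop("gene start < 0")
    if (any(ann$start >= ann$end)) stop("gene start >= end (0-based half-open required)")
    bad <- !ann$strand %in% c("+", "-")
    if (any(bad)) stop("unknown strand symbol: ", paste(unique(ann$strand[bad]), collapse = ", "))
  }
  class(ann) <- unique(c("gene_annotation", class(ann)))
  ann
}

#' Read a gene-level GTF file
#'
#' Imports a GTF (1-based closed intervals) and returns a [gene_annotation()]
#' in 0-based half-open coordinates. When the file carries a `type` column
#' with `"gene"` features, only those rows are kept; otherwise every feature
#' row is treated as one gene-level record (this is how promoter GTFs written
#' by [write_promoter_gtf()] are read back). Duplicate `gene_id`s and strand
#' symbols other than `+`/`-` are rejected.
#'
#' @param path path to a GTF file.
#' @return A `gene_annotation` data.frame.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    return(gene_annotation(character(), character(), integer(), integer(), character()))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0) {
    return(gene_annotation(character(), character(), integer(), integer(), character()))
  }
  if (!is.null(mcols(gr)$type) && any(as.character(mcols(gr)$type) == "gene"))
    gr <- gr[as.character(mcols(gr)$type) == "gene"]
  ids <- mcols(gr)$gene_id
  if (is.null(ids) || anyNA(ids)) stop("GTF records without a gene_id attribute in '", path, "'")
  gene_annotation(gene_id = as.character(ids),
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)))
}

#' Transcription start site of each gene
#'
#' Strand-aware TSS: the 0-based position of the first transcribed base,
#' `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param ann a `gene_annotation`.
#' @return Integer vector named by `gene_id`.
#' @export
tss_of <- function(ann) {
  setNames(ifelse(ann$strand == "+", ann$start, ann$end - 1L), ann$gene_id)
}

#' Build promoter windows around each TSS
#'
#' One window per gene spanning `window_half` bp up- and downstream of the
#' TSS, inclusive of the TSS base: `[tss - window_half, tss + window_half + 1)`
#' in 0-based half-open coordinates, i.e. `2 * window_half + 1` bp when not
#' truncated. Windows are clipped at position 0 (chromosome start); chromosome
#' lengths, when supplied, clip the right edge as well.
#'
#' @param ann a `gene_annotation`.
#' @param window_half half-width in bp (default 1000, giving 2001-bp windows).
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `tss`, `strand`.
#' @export
build_promoter_windows <- function(ann, window_half = 1000L, chrom_sizes = NULL) {
  stopifnot(window_half > 0)
  tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  start <- pmax(0L, as.integer(tss - window_half))
  end <- as.integer(tss + window_half + 1L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[ann$chrom])
    end <- ifelse(is.na(lim), end, pmin(end, as.integer(lim)))
  }
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = start, end = end, tss = as.integer(tss),
             strand = ann$strand, stringsAsFactors = FALSE)
}

#' Write promoter windows as a GTF file
#'
#' Emits one `promoter` feature per window in 1-based closed GTF coordinates,
#' carrying `gene_id` and `tss` attributes, so that reading the file back
#' with [read_gtf()] recovers the windows exactly.
#'
#' @param windows output of [build_promoter_windows()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_gtf <- function(windows, path) {
  stopifnot(nrow(windows) > 0)
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(start = windows$start + 1L, end = windows$end),
                               strand = if (!is.null(windows$strand)) windows$strand else "+")
  mcols(gr)$source <- "regucircuit"
  mcols(gr)$type <- "promoter"
  mcols(gr)$gene_id <- windows$gene_id
  mcols(gr)$tss <- as.integer(windows$tss)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED3/BED5/BED6 dialect, 0-based half-open. Returns a `data.frame` with
#' columns `chrom`, `start`, `end` and, when present in the file, `name`,
#' `score` and `strand`.
#'
#' @param path path to a BED file.
#' @return Interval `data.frame` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$name)) out$name <- as.character(mcols(gr)$name)
  if (!is.null(mcols(gr)$score)) out$score <- as.numeric(mcols(gr)$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  if (any(out$start < 0)) stop("BED '", path, "': negative start coordinate")
  if (any(out$start >= out$end)) stop("BED '", path, "': start >= end")
  out
}

#' Write intervals as a BED file
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns (0-based half-open).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end))
    stop("invalid interval: require 0 <= start < end")
  n <- nrow(intervals)
  df <- data.frame(chrom = intervals$chrom,
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end),
                   name = if (!is.null(intervals$name)) intervals$name else rep(".", n),
                   score = if (!is.null(intervals$score)) intervals$score else rep(0, n),
                   strand = if (!is.null(intervals$strand)) intervals$strand else rep(".", n),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

intervals_to_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(factor(x$chrom, levels = seqlevels),
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# GRanges pair on a shared seqlevel universe (avoids seqinfo-merge warnings)
granges_pair <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  lev <- unique(c(chrom_a, chrom_b))
  list(a = GenomicRanges::GRanges(factor(chrom_a, levels = lev),
                                  IRanges::IRanges(start_a + 1L, end_a)),
       b = GenomicRanges::GRanges(factor(chrom_b, levels = lev),
                                  IRanges::IRanges(start_b + 1L, end_b)))
}

#' Intersect two peak sets (report-A semantics)
#'
#' Returns each interval of `a` that overlaps at least one interval of `b`
#' by at least `min_overlap` bp, in sorted `(chrom, start, end)` order and
#' without duplicates — the default behaviour of `bedtools intersect -u`.
#' With `fragments = TRUE` the overlapping fragments themselves are returned
#' instead (plain `bedtools intersect` semantics).
#'
#' @param a,b interval `data.frame`s (0-based half-open).
#' @param min_overlap minimum overlap in bp (default 1).
#' @param fragments return overlap fragments instead of whole `a` intervals.
#' @return Interval `data.frame`.
#' @export
intersect_common <- function(a, b, min_overlap = 1L, fragments = FALSE) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  gp <- granges_pair(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
  ga <- gp$a; gb <- gp$b
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap)
  if (!fragments) {
    keep <- sort(unique(queryHits(hits)))
    out <- unique(a[keep, c("chrom", "start", "end"), drop = FALSE])
  } else {
    qa <- ga[queryHits(hits)]
    qb <- gb[subjectHits(hits)]
    frag <- IRanges::pintersect(qa, qb)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(frag)),
                      start = GenomicRanges::start(frag) - 1L,
                      end = GenomicRanges::end(frag),
                      stringsAsFactors = FALSE)
    out <- unique(out)
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
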