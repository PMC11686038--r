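# Genomic interval data model and algebra.
#
# Peak sets are plain GRanges. Files use BED conventions (0-based half-open);
# in memory everything is 1-based closed (IRanges convention). Conversion
# happens only in read_peaks()/write_peaks()/read_gene_model().

#' Read a peak file (BED6 or MACS2 narrowPeak)
#'
#' Parses a tab-separated peak file into a sorted `GRanges`. Coordinates in
#' the file are 0-based half-open and are converted to the in-memory 1-based
#' closed convention. Lines with fewer than three columns, non-numeric or
#' negative coordinates, or `start >= end` raise an error naming the line.
#'
#' @param path path to the file.
#' @param dialect `"BED6"` (3-6 columns used) or `"narrowPeak"` (10 columns;
#'   columns 7-10 kept as metadata `signalValue`, `pValue`, `qValue`, `peak`).
#' @return a `GRanges` sorted by (chrom, start, end), with metadata columns
#'   `name` (default `"."`) and `score` (default 0).
#' @export
read_peaks <- function(path, dialect = c("BED6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", which(nf < 3L)[1L], " of ", path,
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
  if (any(bad)) {
    stop("line ", which(bad)[1L], " of ", path,
         ": invalid interval coordinates (need 0 <= start < end)")
  }
  get_col <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, ""), default)
  }
  nm <- get_col(4L, ".")
  sc <- suppressWarnings(as.numeric(get_col(5L, "0")))
  sc[is.na(sc)] <- 0
  strand <- get_col(6L, ".")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  mcols(gr)$name <- nm
  mcols(gr)$score <- sc
  if (dialect == "narrowPeak") {
    if (any(nf < 10L)) {
      stop("line ", which(nf < 10L)[1L], " of ", path,
           ": narrowPeak requires 10 columns")
    }
    mcols(gr)$signalValue <- as.numeric(get_col(7L, "0"))
    mcols(gr)$pValue <- as.numeric(get_col(8L, "-1"))
    mcols(gr)$qValue <- as.numeric(get_col(9L, "-1"))
    mcols(gr)$peak <- as.integer(get_col(10L, "-1"))
  }
  sort_peaks(gr)
}

# (chrom, start, end) order, strand ignored; chrom order is alphabetical and
# stable across sessions (no factor-level dependence on input order).
sort_peaks <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

#' Write a peak set to a BED6 or narrowPeak file
#'
#' Inverse of [read_peaks()]: `read_peaks(write_peaks(x))` reproduces `x`
#' exactly (coordinates, names, scores) for sorted input.
#'
#' @param peaks a `GRanges`.
#' @param path output path.
#' @param dialect `"BED6"` or `"narrowPeak"`.
#' @export
write_peaks <- function(peaks, path, dialect = c("BED6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  nm <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name else rep(".", length(peaks))
  sc <- if (!is.null(mcols(peaks)$score)) mcols(peaks)$score else rep(0, length(peaks))
  str <- as.character(GenomicRanges::strand(peaks))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   name = nm, score = sc, strand = str)
  if (dialect == "narrowPeak") {
    df$signalValue <- mcols(peaks)$signalValue %||% rep(0, length(peaks))
    df$pValue <- mcols(peaks)$pValue %||% rep(-1, length(peaks))
    df$qValue <- mcols(peaks)$qValue %||% rep(-1, length(peaks))
    df$peak <- mcols(peaks)$peak %||% rep(-1L, length(peaks))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Empty peak set with the standard name/score metadata columns, so it can
# be combined with non-empty sets.
empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr)$name <- character(0)
  mcols(gr)$score <- numeric(0)
  gr
}

#' Merge intervals within a gap
#'
#' Collapses a peak set to pairwise non-overlapping intervals: any two
#' intervals overlapping or separated by at most `gap` bases are merged.
#' Bookended intervals (`[a,b)`, `[b,c)`) merge at `gap = 0`. Idempotent;
#' conserves covered bases at `gap = 0`.
#'
#' @param peaks a `GRanges`.
#' @param gap maximum separation (bp) at which two intervals still merge.
#' @return sorted, non-overlapping `GRanges` (metadata dropped).
#' @export
merge_intervals <- function(peaks, gap = 0L) {
  if (length(gap) != 1L || is.na(gap) || gap < 0) stop("gap must be >= 0")
  sort_peaks(GenomicRanges::reduce(peaks, min.gapwidth = gap + 1L,
                                   ignore.strand = TRUE))
}

#' Overlap hit vector
#'
#' For each interval of `a`, whether some interval of `b` shares at least
#' `min_bp` bases with it (strand-blind, half-open file semantics: peaks
#' abutting at a single boundary base do not overlap).
#'
#' @param a,b `GRanges`.
#' @param min_bp minimum shared bases (>= 1).
#' @return logical vector along `a`.
#' @export
peak_overlaps <- function(a, b, min_bp = 1L) {
  if (length(min_bp) != 1L || is.na(min_bp) || min_bp < 1) stop("min_bp must be >= 1")
  # seqlevel merging between unrelated peak sets is intended, not a problem
  suppressWarnings(
    GenomicRanges::countOverlaps(a, b, minoverlap = min_bp,
                                 ignore.strand = TRUE) > 0L)
}

#' Read a gene model (TSV or GTF-lite)
#'
#' TSV format (with header): `gene_id`, `chrom`, `strand`, `gene_start`,
#' `gene_end` (0-based half-open), optional `exon_starts`, `exon_ends`
#' (comma-separated, 0-based half-open). GTF: 1-based inclusive; `gene`
#' rows required, `exon` rows optional (genes without exon rows get their
#' full span as one exon); `gene_id "..."` must be present in column 9.
#'
#' The transcription start site is the strand-aware 5' end: `gene_start`
#' for `+` genes, `gene_end - 1` (0-based) for `-` genes.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.gtf`/`.gff` vs TSV), `"tsv"`,
#'   or `"gtf"`.
#' @return a `GeneModel`: list with `genes` (data.frame: gene_id, chrom,
#'   strand, start, end, tss — all 1-based closed) and `exons` (`GRanges`
#'   with `gene_id`).
#' @export
read_gene_model <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     quote = "", comment.char = "")
    need <- c("gene_id", "chrom", "strand", "gene_start", "gene_end")
    if (!all(need %in% names(df))) {
      stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    }
    genes <- data.frame(gene_id = as.character(df$gene_id),
                        chrom = as.character(df$chrom),
                        strand = as.character(df$strand),
                        start = df$gene_start + 1L, end = df$gene_end,
                        stringsAsFactors = FALSE)
    if ("exon_starts" %in% names(df) && "exon_ends" %in% names(df)) {
      es <- lapply(strsplit(as.character(df$exon_starts), ","), as.integer)
      ee <- lapply(strsplit(as.character(df$exon_ends), ","), as.integer)
      n_ex <- lengths(es)
      exons <- GenomicRanges::GRanges(rep(genes$chrom, n_ex),
                                      IRanges(unlist(es) + 1L, unlist(ee)),
                                      strand = rep(genes$strand, n_ex))
      mcols(exons)$gene_id <- rep(genes$gene_id, n_ex)
    } else {
      exons <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges(genes$start, genes$end),
                                      strand = genes$strand)
      mcols(exons)$gene_id <- genes$gene_id
    }
  } else {
    df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                     quote = "", comment.char = "#",
                     col.names = c("seqname", "source", "feature", "start",
                                   "end", "score", "strand", "frame", "attr"))
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", df$attr)
    if (any(!grepl('gene_id "', df$attr, fixed = TRUE))) {
      stop("GTF attributes must contain gene_id \"...\"")
    }
    g <- df[df$feature == "gene", ]
    if (nrow(g) == 0L) stop("GTF contains no 'gene' features")
    genes <- data.frame(gene_id = gid[df$feature == "gene"],
                        chrom = g$seqname, strand = g$strand,
                        start = g$start, end = g$end,
                        stringsAsFactors = FALSE)
    e <- df[df$feature == "exon", ]
    eg <- gid[df$feature == "exon"]
    missing_ex <- setdiff(genes$gene_id, eg)
    add <- genes[genes$gene_id %in% missing_ex, ]
    ex_chrom <- c(e$seqname, add$chrom)
    ex_start <- c(e$start, add$start)
    ex_end <- c(e$end, add$end)
    ex_strand <- c(e$strand, add$strand)
    ex_gid <- c(eg, add$gene_id)
    exons <- GenomicRanges::GRanges(ex_chrom, IRanges(ex_start, ex_end),
                                    strand = ex_strand)
    mcols(exons)$gene_id <- ex_gid
  }
  if (nrow(genes) == 0L) stop("empty gene model")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene model")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(genes$start > genes$end)) stop("gene with start > end")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Peak midpoint as a 1-based position: midpoint of [start0, end0) is
# (start0 + end0) %/% 2 in 0-based coords.
peak_midpoints <- function(peaks) {
  (GenomicRanges::start(peaks) - 1L + GenomicRanges::end(peaks)) %/% 2L + 1L
}

# For each (chrom, pos) query, the nearest TSS in the model; ties on |d|
# (and TSSs sharing a position) resolved to the lexicographically smallest
# gene_id. Returns list(gene_id, distance) with signed strand-aware distance
# (positive = downstream of the TSS). NA gene for chromosomes with no genes.
nearest_tss <- function(chrom, pos, model) {
  genes <- model$genes
  out_gene <- rep(NA_character_, length(pos))
  out_dist <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0L) next
    g <- g[order(g$tss, g$gene_id), ]
    p <- pos[qi]
    right <- findInterval(p, g$tss) + 1L   # first tss >= p is at `right` or beyond
    left <- right - 1L
    pick <- integer(length(p))
    for (k in seq_along(p)) {
      cand <- c(if (left[k] >= 1L) left[k], if (right[k] <= nrow(g)) right[k])
      d <- abs(g$tss[cand] - p[k])
      cand <- cand[d == min(d)]
      # duplicates at the same tss position sit adjacently; scan the run of
      # equal-|d| entries around each candidate and take the smallest gene_id
      best <- min(d)
      run <- which(abs(g$tss - p[k]) == best)
      pick[k] <- run[order(g$gene_id[run])[1L]]
    }
    sgn <- ifelse(g$strand[pick] == "+", 1L, -1L)
    out_gene[qi] <- g$gene_id[pick]
    out_dist[qi] <- sgn * (p - g$tss[pick])
  }
  list(gene_id = out_gene, distance = out_dist)
}

FEATURE_CATEGORIES <- c("promoter_le1kb", "promoter_1to2kb", "promoter_2to3kb",
                        "exon", "intron", "downstream", "distal_intergenic")

#' Annotate peaks to the nearest gene
#'
#' Assigns each peak (by its midpoint) to the nearest transcription start
#' site and to exactly one feature category, with precedence promoter bins
#' (<=1 kb, 1-2 kb, 2-3 kb around the TSS) > exon > intron > downstream
#' (within 3 kb past the strand-aware gene end) > distal intergenic.
#' Distances are signed and strand-aware (positive = downstream of the TSS).
#' Peaks on chromosomes absent from the model are `distal_intergenic` with
#' no gene.
#'
#' @param peaks a `GRanges`.
#' @param model a `GeneModel` from [read_gene_model()].
#' @param promoter_window outer promoter bound in bp (default 3000; the
#'   promoter bins are fixed at 1 kb steps up to this bound).
#' @return data.frame with one row per peak: `chrom`, `start`, `end`
#'   (0-based half-open, as in the source file), `gene_id`,
#'   `distance_to_tss`, `category` (factor over the seven categories).
#' @export
annotate_to_genes <- function(peaks, model, promoter_window = 3000L) {
  stopifnot(is(model, "GeneModel"))
  if (nrow(model$genes) == 0L) stop("empty gene model")
  n <- length(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid <- peak_midpoints(peaks)
  nt <- nearest_tss(chrom, mid, model)
  cat <- rep("distal_intergenic", n)
  absd <- abs(nt$distance)
  cat[!is.na(absd) & absd <= 1000L] <- "promoter_le1kb"
  cat[!is.na(absd) & absd > 1000L & absd <= 2000L] <- "promoter_1to2kb"
  cat[!is.na(absd) & absd > 2000L & absd <= promoter_window] <- "promoter_2to3kb"

  todo <- which(cat == "distal_intergenic" & !is.na(nt$gene_id))
  if (length(todo)) {
    midgr <- GenomicRanges::GRanges(chrom[todo], IRanges(mid[todo], mid[todo]))
    in_exon <- suppressWarnings(GenomicRanges::countOverlaps(
      midgr, model$exons, ignore.strand = TRUE)) > 0L
    genes_gr <- GenomicRanges::GRanges(model$genes$chrom,
                                       IRanges(model$genes$start, model$genes$end))
    in_gene <- suppressWarnings(GenomicRanges::countOverlaps(
      midgr, genes_gr, ignore.strand = TRUE)) > 0L
    # downstream: within 3 kb past the strand-aware 3' end of some gene
    g <- model$genes
    ds_start <- ifelse(g$strand == "+", g$end + 1L, pmax(1L, g$start - 3000L))
    ds_end <- ifelse(g$strand == "+", g$end + 3000L, g$start - 1L)
    ok <- ds_start <= ds_end
    ds_gr <- GenomicRanges::GRanges(g$chrom[ok], IRanges(ds_start[ok], ds_end[ok]))
    in_ds <- suppressWarnings(GenomicRanges::countOverlaps(
      midgr, ds_gr, ignore.strand = TRUE)) > 0L
    cat[todo[in_exon]] <- "exon"
    cat[todo[!in_exon & in_gene]] <- "intron"
    cat[todo[!in_exon & !in_gene & in_ds]] <- "downstream"
  }
  data.frame(chrom = chrom,
             start = GenomicRanges::start(peaks) - 1L,
             end = GenomicRanges::end(peaks),
             gene_id = nt$gene_id,
             distance_to_tss = nt$distance,
             category = factor(cat, levels = FEATURE_CATEGORIES),
             stringsAsFactors = FALSE)
}
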