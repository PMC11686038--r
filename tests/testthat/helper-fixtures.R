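# Shared helpers: small random inputs and independent brute-force oracles.
# Oracles are deliberately naive (all-pairs scans, base-resolution bit
# vectors, literal tables) and never call the code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr_of <- function(chrom, start0, end0, name = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  mcols(gr)$name <- name %||% paste0("p", seq_along(gr))
  mcols(gr)$score <- rep(0, length(gr))
  gr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_peaks <- function(n, chroms = c("chrA", "chrB"), max_pos = 2e5,
                         max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(start, start + width - 1))
  mcols(gr)$name <- paste0("p", seq_len(n))
  mcols(gr)$score <- rep(0, n)
  gr
}

# all-pairs overlap oracle: does a[i] share >= min_bp bases with any b?
bf_overlaps <- function(a, b, min_bp = 1) {
  ac <- as.character(seqnames(a)); bc <- as.character(seqnames(b))
  as_ <- start(a); ae <- end(a); bs <- start(b); be <- end(b)
  vapply(seq_along(a), function(i) {
    j <- which(bc == ac[i])
    if (!length(j)) return(FALSE)
    any(pmin(ae[i], be[j]) - pmax(as_[i], bs[j]) + 1 >= min_bp)
  }, logical(1))
}

# base-resolution union length over one or more peak sets
bf_union_bases <- function(grs) {
  if (is(grs, "GRanges")) grs <- list(grs)
  pooled <- do.call(rbind, lapply(grs, function(g) {
    data.frame(chrom = as.character(seqnames(g)), start = start(g), end = end(g))
  }))
  total <- 0L
  for (ch in unique(pooled$chrom)) {
    p <- pooled[pooled$chrom == ch, ]
    cov <- logical(max(p$end))
    for (i in seq_len(nrow(p))) cov[p$start[i]:p$end[i]] <- TRUE
    total <- total + sum(cov)
  }
  total
}

# literal truth table for the 16 closed-at-start / open-at-end six-stage
# patterns, written out by hand from the class definitions
co_truth_table <- function() {
  data.frame(
    pattern = c("011111", "001111", "010111", "000111",
                "011011", "001011", "010011", "000011",
                "011101", "001101", "010101", "000101",
                "011001", "001001", "010001", "000001"),
    class = c("CO1", "CO2", "CO3", "CO3",
              "CO4", "CO4", "CO4", "CO4",
              "CO5", "CO5", "CO5", "CO5",
              "CO5", "CO5", "CO5", "CO5"),
    stringsAsFactors = FALSE)
}

bits_of <- function(s) as.logical(as.integer(strsplit(s, "")[[1]]))

# independent classifier written from the definition text: find the
# earliest stage from which the state is permanent, by explicit scan
oracle_classify <- function(bits) {
  n <- length(bits)
  if (!bits[1] && bits[n]) {
    for (j in 2:n) if (all(bits[j:n])) return(paste0("CO", j - 1))
  }
  if (bits[1] && !bits[n]) {
    for (j in 2:n) if (all(!bits[j:n])) return(paste0("OC", j - 1))
  }
  if (bits[1] && bits[n]) return(if (all(bits)) "PO" else "PO_UNSTABLE")
  if (any(bits)) "TRANSIENT" else "NEVER_OPEN"
}

all_patterns <- function(n = 6) {
  as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
}

# small gene model built in code: three + strand genes and one - strand
toy_gene_model <- function(dir = withr::local_tempdir()) {
  path <- file.path(dir, "toy_genes.tsv")
  df <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "-", "+"),
    gene_start = c(10000L, 50000L, 80000L, 5000L),
    gene_end = c(20000L, 60000L, 90000L, 9000L),
    exon_starts = c("10000,15000", "50000", "80000,86000", "5000"),
    exon_ends = c("12000,20000", "60000", "82000,90000", "9000"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_gene_model(path)
}

# scaled-down fixture configuration for unit tests
small_fixture_config <- function(...) {
  base <- fixture_config(
    chromosomes = c(chr1 = 2e6, chr2 = 1e6, chr3 = 4e6),
    cads = list(regions_per_class = 10L),
    binding = list(cobind = c(lost = 8L, common = 12L, gained = 20L),
                   decoys_per_set = 10L,
                   bound_up = 10L, bound_down = 15L, bound_null = 20L),
    genes = list(n_genes = 300L),
    expression = list(genes_per_cluster = 2L))
  utils::modifyList(base, list(...))
}

count_de_table <- function(em, systems, stages, control = "DsRed", ...) {
  do.call(rbind, lapply(systems, function(s) {
    do.call(rbind, lapply(stages, function(t) call_de(em, s, t, control, ...)))
  }))
}
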