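# Cross-system differential-expression classification: median-of-ratios
# normalisation, a built-in per-stage DE caller, the both-direction
# exclusion rule, 7 system-combinations x 3 endpoint fold-change bins
# (UC1-UC21 / DC1-DC21), the single-system C1-C6 variant, and within-cluster
# ranking by peak stage.

SYSTEM_ORDER <- c("S4", "O4", "O+S")

# Fixed combination order for cluster labels: all-three, S4+O+S, O4+O+S,
# S4+O4, O+S only, S4 only, O4 only.
COMBINATION_ORDER <- c("S4/O4/O+S", "S4/O+S", "O4/O+S", "S4/O4",
                       "O+S", "S4", "O4")

RATIO_BINS <- c("high", "mid", "low")

#' Construct an expression matrix with sample metadata
#'
#' @param counts numeric matrix of non-negative gene-level counts; rownames
#'   are gene ids, colnames are sample ids.
#' @param samples data.frame with columns `sample`, `system`, `stage`,
#'   `replicate`; `sample` must match `colnames(counts)`.
#' @return an `ExpressionMatrix`: list with `counts`, `samples`,
#'   `normalized` flag and (after normalisation) `size_factors`.
#' @export
expression_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("sample", "system", "stage", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(samples$sample, colnames(counts))) {
    stop("sample sheet does not match count matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples,
                 normalized = FALSE, size_factors = NULL),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples", if (x$normalized) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Median-of-ratios normalisation
#'
#' Computes per-sample size factors as the median ratio of a sample's counts
#' to the per-gene geometric mean, over genes with a finite geometric mean
#' and a nonzero count in that sample, and divides counts by them.
#'
#' @param m a raw `ExpressionMatrix`.
#' @return the normalised `ExpressionMatrix` (with `size_factors` set).
#' @export
normalize_counts <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (m$normalized) return(m)
  cnt <- m$counts
  if (any(colSums(cnt) == 0)) stop("sample with all-zero counts")
  loggeo <- rowMeans(log(cnt))
  sf <- apply(cnt, 2L, function(x) {
    r <- (log(x) - loggeo)[is.finite(loggeo) & x > 0]
    if (length(r) == 0L) stop("cannot compute size factor: no usable genes")
    exp(median(r))
  })
  m$counts <- sweep(cnt, 2L, sf, "/")
  m$size_factors <- sf
  m$normalized <- TRUE
  m
}

group_columns <- function(m, system, stage) {
  which(m$samples$system == system & m$samples$stage == stage)
}

#' Call differential expression for one (system, stage) vs the control system
#'
#' Log2 fold changes use a pseudocount of 1 on normalised group means.
#' With at least two replicates per group, tests run on
#' `log2(normalized + 1)`: the default `"moderated"` method fits a
#' two-group linear model per gene and applies empirical-Bayes variance
#' moderation with a mean-variance trend (limma), which is the standard
#' remedy for the unstable per-gene variances of 3-replicate designs;
#' `"welch"` is a plain per-gene two-sided Welch t-test. P-values are
#' Benjamini-Hochberg adjusted across tested genes. With a single
#' replicate in either group the caller falls back to fold-change-only
#' mode (`padj` 0 when `|log2FC|` clears the threshold, 1 otherwise).
#' Genes below `min_mean` average normalised counts are not tested
#' (`padj` NA, direction `ns`).
#'
#' @param m a normalised `ExpressionMatrix`.
#' @param system,stage the treatment group.
#' @param control_system the control system compared at the same stage.
#' @param lfc_threshold minimum `|log2FC|` for a call (default 1, i.e.
#'   2-fold).
#' @param alpha adjusted-p cutoff.
#' @param min_mean minimum average normalised count across the two groups.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame: `gene`, `system`, `stage`, `log2FC`, `padj`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
call_de <- function(m, system, stage, control_system,
                    lfc_threshold = 1.0, alpha = 0.05, min_mean = 10,
                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(is(m, "ExpressionMatrix"))
  if (!m$normalized) stop("call_de expects a normalised ExpressionMatrix")
  ti <- group_columns(m, system, stage)
  ci <- group_columns(m, control_system, stage)
  if (length(ti) == 0L) stop("unknown group: ", system, "/", stage)
  if (length(ci) == 0L) stop("unknown group: ", control_system, "/", stage)
  trt <- m$counts[, ti, drop = FALSE]
  ctl <- m$counts[, ci, drop = FALSE]
  mt <- rowMeans(trt)
  mc <- rowMeans(ctl)
  lfc <- log2((mt + 1) / (mc + 1))
  tested <- (mt + mc) / 2 >= min_mean
  padj <- rep(NA_real_, nrow(m$counts))
  if (length(ti) >= 2L && length(ci) >= 2L) {
    lt <- log2(trt + 1)
    lc <- log2(ctl + 1)
    if (method == "moderated") {
      expr <- cbind(lt, lc)
      design <- cbind(Intercept = 1,
                      group = rep(c(1, 0), c(ncol(lt), ncol(lc))))
      fit <- limma::lmFit(expr, design)
      fit <- limma::eBayes(fit, trend = nrow(expr) >= 50L)
      p <- fit$p.value[, "group"]
    } else {
      n1 <- ncol(lt); n2 <- ncol(lc)
      m1 <- rowMeans(lt); m2 <- rowMeans(lc)
      v1 <- rowSums((lt - m1)^2) / (n1 - 1)
      v2 <- rowSums((lc - m2)^2) / (n2 - 1)
      se2 <- v1 / n1 + v2 / n2
      tstat <- ifelse(se2 == 0, ifelse(m1 == m2, 0, Inf), (m1 - m2) / sqrt(se2))
      df <- ifelse(se2 == 0, 1,
                   se2^2 / (pmax((v1 / n1)^2 / (n1 - 1), .Machine$double.xmin) +
                            pmax((v2 / n2)^2 / (n2 - 1), .Machine$double.xmin)))
      p <- ifelse(is.infinite(tstat), 0, 2 * pt(-abs(tstat), df = df))
    }
    padj[tested] <- p.adjust(p[tested], method = "BH")
  } else {
    padj[tested] <- ifelse(abs(lfc[tested]) >= lfc_threshold, 0, 1)
  }
  direction <- rep("ns", nrow(m$counts))
  sig <- !is.na(padj) & padj <= alpha
  direction[sig & lfc >= lfc_threshold] <- "up"
  direction[sig & lfc <= -lfc_threshold] <- "down"
  data.frame(gene = rownames(m$counts), system = system, stage = stage,
             log2FC = lfc, padj = padj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an external differential-expression table
#'
#' Accepts tab-separated output of a standard DE engine with columns `gene`,
#' `log2FC` (alias `log2FoldChange`) and `padj`, and assigns directions with
#' the same thresholds as the built-in caller. `padj = NA` rows are `ns`.
#'
#' @param path TSV path with a header line.
#' @param system,stage labels attached to the rows.
#' @inheritParams call_de
#' @return data.frame in the [call_de()] layout.
#' @export
read_external_de <- function(path, system = NA_character_, stage = NA_character_,
                             lfc_threshold = 1.0, alpha = 0.05) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if ("log2FoldChange" %in% names(df) && !"log2FC" %in% names(df)) {
    names(df)[names(df) == "log2FoldChange"] <- "log2FC"
  }
  need <- c("gene", "log2FC", "padj")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene in DE table: ", path)
  direction <- rep("ns", nrow(df))
  sig <- !is.na(df$padj) & df$padj <= alpha
  direction[sig & df$log2FC >= lfc_threshold] <- "up"
  direction[sig & df$log2FC <= -lfc_threshold] <- "down"
  data.frame(gene = as.character(df$gene), system = system, stage = stage,
             log2FC = df$log2FC, padj = df$padj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Integrate per-stage DE calls for one system
#'
#' Unions up- and down-calls across stages and applies the both-direction
#' exclusion rule: genes called up at one stage and down at another within
#' the same system are excluded from both sets.
#'
#' @param tables data.frame of [call_de()] rows over the system's stages
#'   (rows of other systems are ignored when `system` is given).
#' @param system system id (default: the single system present).
#' @return a `SystemDirectionSets`: list with `system`, `up`, `down`,
#'   `excluded` character vectors of gene ids.
#' @export
integrate_system_de <- function(tables, system = NULL) {
  if (!is.null(system)) tables <- tables[tables$system %in% system, ]
  if (nrow(tables) == 0L) stop("no DE rows for system: ", system)
  raw_up <- unique(tables$gene[tables$direction == "up"])
  raw_down <- unique(tables$gene[tables$direction == "down"])
  excluded <- intersect(raw_up, raw_down)
  structure(list(system = system %||% unique(tables$system),
                 up = sort(setdiff(raw_up, excluded)),
                 down = sort(setdiff(raw_down, excluded)),
                 excluded = sort(excluded)),
            class = "SystemDirectionSets")
}

#' @export
print.SystemDirectionSets <- function(x, ...) {
  cat("SystemDirectionSets", x$system, "- up:", length(x$up),
      "down:", length(x$down), "excluded:", length(x$excluded), "\n")
  invisible(x)
}

#' Cross-system combination assignment
#'
#' Maps every gene carrying the given direction in at least one system to
#' the exact subset of systems in which it carries that direction ("common
#' up" when shared, "specific up" when unique). Genes carrying the opposite
#' direction in any other system are dropped from the map entirely.
#'
#' @param sets named list of `SystemDirectionSets`, one per system (names
#'   are the system ids, e.g. `S4`, `O4`, `O+S`).
#' @param direction `"up"` or `"down"`.
#' @return data.frame: `gene`, `combination` (label joining system ids with
#'   `/` in the fixed order S4, O4, O+S).
#' @export
classify_cross_system <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  systems <- names(sets)
  stopifnot(!is.null(systems), all(nzchar(systems)))
  with_dir <- lapply(sets, function(s) s[[direction]])
  opposite <- unique(unlist(lapply(sets, function(s) {
    s[[setdiff(c("up", "down"), direction)]]
  })))
  genes <- setdiff(unique(unlist(with_dir)), opposite)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), combination = character(0),
                      stringsAsFactors = FALSE))
  }
  member <- vapply(with_dir, function(g) genes %in% g, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, systems))
  ord <- intersect(SYSTEM_ORDER, systems)
  ord <- c(ord, setdiff(systems, ord))
  combo <- apply(member[, ord, drop = FALSE], 1L,
                 function(r) paste(ord[r], collapse = "/"))
  data.frame(gene = genes, combination = combo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Endpoint (ESC/MEF) ratio bin
#'
#' Bins a gene by its normalised expression ratio between the reprogramming
#' endpoint (ESC) and start (MEF): `high` when
#' `(esc + pc)/(mef + pc) >= 2`, `low` when `<= 0.5`, `mid` otherwise.
#' Boundary values land in `high`/`low` (the legends use >= and <=).
#'
#' @param esc_mean,mef_mean normalised mean counts (vectors allowed).
#' @param pseudocount added to both means (default 1).
#' @return factor over `high`, `mid`, `low`.
#' @export
bin_by_endpoint_ratio <- function(esc_mean, mef_mean, pseudocount = 1) {
  if (any(esc_mean < 0) || any(mef_mean < 0)) stop("means must be >= 0")
  ratio <- (esc_mean + pseudocount) / (mef_mean + pseudocount)
  bin <- ifelse(ratio >= 2, "high", ifelse(ratio <= 0.5, "low", "mid"))
  factor(bin, levels = RATIO_BINS)
}

#' Assemble cluster labels
#'
#' Joins combination assignments and ratio bins into cluster labels. In
#' cross-system mode the 7 combinations (ordered all-three, S4/O+S, O4/O+S,
#' S4/O4, O+S, S4, O4) x 3 bins (high, mid, low) give `UC1..UC21` for up
#' and `DC1..DC21` for down. In single-system mode (one system vs control)
#' bins map to `C1-C3` (up) and `C4-C6` (down).
#'
#' @param combinations data.frame from [classify_cross_system()] (ignored in
#'   single-system mode, where every gene uses the single system).
#' @param bins named factor/character of ratio bins keyed by gene (see
#'   [bin_by_endpoint_ratio()]); every classified gene must be present.
#' @param direction `"up"` or `"down"`.
#' @param mode `"cross_system"` or `"single_system"`.
#' @return data.frame: `gene`, `direction`, `combination`, `bin`, `label`.
#' @export
assemble_clusters <- function(combinations, bins, direction = c("up", "down"),
                              mode = c("cross_system", "single_system")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  genes <- combinations$gene
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), direction = character(0),
                      combination = character(0), bin = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (!all(genes %in% names(bins))) {
    stop("missing ratio bin for: ",
         paste(head(setdiff(genes, names(bins))), collapse = ", "))
  }
  bi <- match(as.character(bins[genes]), RATIO_BINS)
  if (mode == "cross_system") {
    ci <- match(combinations$combination, COMBINATION_ORDER)
    if (anyNA(ci)) {
      stop("unknown combination: ",
           paste(unique(combinations$combination[is.na(ci)]), collapse = ", "))
    }
    label <- paste0(if (direction == "up") "UC" else "DC", (ci - 1L) * 3L + bi)
  } else {
    label <- paste0("C", if (direction == "up") bi else 3L + bi)
  }
  data.frame(gene = genes, direction = direction,
             combination = combinations$combination,
             bin = as.character(bins[genes]), label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Order genes within a cluster by their peak stage
#'
#' Groups genes by the stage at which their mean normalised expression in
#' the given system is highest (lowest for down-clusters), orders stage
#' groups along the axis, and breaks ties by gene id.
#'
#' @param genes character vector of cluster member genes.
#' @param m a normalised `ExpressionMatrix`.
#' @param system system whose time course is used.
#' @param direction `"up"` (peak = argmax) or `"down"` (peak = argmin).
#' @param stages stages of the system used, in axis order (default: the
#'   stages present for that system, in sample-sheet order of first
#'   appearance).
#' @return data.frame in rank order: `gene`, `peak_stage`, `rank`.
#' @export
rank_within_cluster <- function(genes, m, system, direction = c("up", "down"),
                                stages = NULL) {
  direction <- match.arg(direction)
  stopifnot(is(m, "ExpressionMatrix"))
  if (!all(genes %in% rownames(m$counts))) {
    stop("cluster genes missing from the expression matrix")
  }
  if (is.null(stages)) {
    stages <- unique(m$samples$stage[m$samples$system == system])
  }
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), peak_stage = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  means <- vapply(stages, function(t) {
    rowMeans(m$counts[genes, group_columns(m, system, t), drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1L) means <- matrix(means, nrow = 1L)
  peak <- if (direction == "up") max.col(means, ties.method = "first")
          else max.col(-means, ties.method = "first")
  ord <- order(peak, genes)
  data.frame(gene = genes[ord], peak_stage = stages[peak][ord],
             rank = seq_along(genes), row.names = NULL,
             stringsAsFactors = FALSE)
}
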