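# Synthetic-data generator: genome, gene model, per-(system, stage) ATAC
# peak sets with planted trajectory classes, factor-binding peaks with
# planted direct/indirect and co-binding structure, and negative-binomial
# count matrices with planted cross-system DE clusters. Every planted unit
# is recorded in a truth table, the oracle for recovery tests.

#' Default fixture configuration
#'
#' Returns the configuration of the synthetic study: a three-chromosome
#' genome (CADs regions, co-binding regions, genes), four reprogramming
#' systems over the six-stage axis, 100 regions planted per named
#' trajectory class per system, binding with a 0.5 direct fraction and a
#' planted predicted/actual co-binding structure (40 lost / 60 common /
#' 100 gained), and a 2,000-gene expression matrix with 10 genes planted
#' per (direction x combination x bin) cluster at 4-fold effects, NB
#' dispersion 0.05, 3 replicates per sample.
#'
#' @param ... named overrides, replacing elements of the nested default
#'   list (e.g. `cads = list(jitter_sd = 50, dropout = 0.05)` replaces only
#'   those two fields).
#' @return nested configuration list.
#' @export
fixture_config <- function(...) {
  cfg <- list(
    chromosomes = c(chr1 = 12e6, chr2 = 4e6, chr3 = 24e6),
    stages = DEFAULT_STAGES,
    systems = DEFAULT_SYSTEMS,
    cads = list(
      chrom = "chr1",
      classes = c("PO", paste0("CO", 1:5), paste0("OC", 1:5)),
      regions_per_class = 100L,
      peak_width_mean = 400, peak_width_sd = 50,
      min_gap = 600, max_gap = 1400,
      jitter_sd = 0, dropout = 0),
    binding = list(
      chrom = "chr2",
      factors = list(SALL4 = c("S4", "O+S"), OCT4 = c("O4", "O+S")),
      direct_fraction = 0.5,
      cobind = c(lost = 40L, common = 60L, gained = 100L),
      decoys_per_set = 50L,
      bound_up = 50L, bound_down = 80L, bound_null = 170L,
      promoter_halfwidth = 100L),
    genes = list(
      chrom = "chr3", n_genes = 2000L,
      min_width = 2000, max_width = 8000,
      min_gap = 1000, max_gap = 5000),
    expression = list(
      genes_per_cluster = 10L,
      effect_lfc = 2,
      dispersion = 0.05,
      replicates = 3L,
      lib_range = c(0.7, 1.3),
      planted_meanlog = log(100), planted_sdlog = 0.3,
      null_meanlog = log(60), null_sdlog = 1))
  modifyList(cfg, list(...))
}

# Canonical occupancy pattern of a planted class over the stage axis.
canonical_pattern <- function(class, n_stages = 6L) {
  if (class == "PO") return(rep(TRUE, n_stages))
  k <- as.integer(sub("^(CO|OC)", "", class))
  if (startsWith(class, "CO")) c(rep(FALSE, k), rep(TRUE, n_stages - k))
  else c(rep(TRUE, k), rep(FALSE, n_stages - k))
}

# Sequential non-overlapping interval layout; errors when the chromosome is
# exhausted. Returns 1-based closed start/end vectors.
layout_intervals <- function(n, widths, gaps, chrom_len, what = "interval") {
  start <- cumsum(c(1 + gaps[1], widths[-n] + gaps[-1]))
  end <- start + widths - 1
  if (end[n] > chrom_len) {
    stop("cannot fit ", n, " ", what, "s into ", chrom_len, " bp")
  }
  list(start = as.integer(start), end = as.integer(end))
}

#' Generate the synthetic genome and gene model
#'
#' Lays out non-overlapping genes with random widths, gaps, strands and 1-3
#' exons on the gene chromosome. Deterministic under `seed`.
#'
#' @param cfg a [fixture_config()] list.
#' @param seed integer seed.
#' @return a `GeneModel`.
#' @export
make_genome_and_genes <- function(cfg = fixture_config(), seed = 1L) {
  g <- cfg$genes
  if (g$n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(seed)
  n <- g$n_genes
  widths <- round(runif(n, g$min_width, g$max_width))
  gaps <- round(runif(n, g$min_gap, g$max_gap))
  pos <- layout_intervals(n, widths, gaps, cfg$chromosomes[[g$chrom]], "gene")
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(n))
  n_ex <- sample(1:3, n, replace = TRUE)
  exons <- lapply(seq_len(n), function(i) {
    if (n_ex[i] == 1L) return(cbind(pos$start[i], pos$end[i]))
    cuts <- sort(sample(seq(pos$start[i] + 1L, pos$end[i] - 1L),
                        2L * (n_ex[i] - 1L)))
    bounds <- c(pos$start[i], cuts, pos$end[i])
    idx <- seq(1L, length(bounds), by = 2L)
    cbind(bounds[idx], bounds[idx + 1L])
  })
  genes <- data.frame(gene_id = gene_id, chrom = g$chrom, strand = strand,
                      start = pos$start, end = pos$end,
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)
  ex_n <- vapply(exons, nrow, 0L)
  ex <- do.call(rbind, exons)
  exons_gr <- GenomicRanges::GRanges(g$chrom, IRanges(ex[, 1L], ex[, 2L]),
                                     strand = rep(strand, ex_n))
  mcols(exons_gr)$gene_id <- rep(gene_id, ex_n)
  structure(list(genes = genes, exons = exons_gr), class = "GeneModel")
}

#' Plant trajectory-class regions and emit per-sample ATAC peaks
#'
#' Lays out disjoint regions on the CADs chromosome and assigns each a
#' (system, class) label; a sample (system, stage) receives a peak at a
#' region exactly when the region belongs to that system and its class's
#' canonical pattern is open at that stage. Peak boundaries are jittered by
#' `N(0, jitter_sd)` and open calls are dropped with probability `dropout`
#' (both zero by default: noiseless mode).
#'
#' @param cfg a [fixture_config()] list.
#' @param seed integer seed.
#' @return list with `atac` (nested `[[system]][[stage]]` `GRanges`) and
#'   `truth` (data.frame: region_id, chrom, start, end (0-based half-open),
#'   system, class).
#' @export
plant_cads <- function(cfg = fixture_config(), seed = 1L) {
  cc <- cfg$cads
  stages <- cfg$stages
  systems <- cfg$systems
  set.seed(seed)
  lab <- expand.grid(system = systems, class = cc$classes,
                     stringsAsFactors = FALSE)
  lab <- lab[rep(seq_len(nrow(lab)), each = cc$regions_per_class), ]
  n <- nrow(lab)
  lab <- lab[sample.int(n), ]  # scatter labels across the chromosome
  widths <- pmax(150, round(rnorm(n, cc$peak_width_mean, cc$peak_width_sd)))
  gaps <- round(runif(n, cc$min_gap, cc$max_gap))
  pos <- layout_intervals(n, widths, gaps, cfg$chromosomes[[cc$chrom]],
                          "region")
  truth <- data.frame(region_id = sprintf("R%05d", seq_len(n)),
                      chrom = cc$chrom,
                      start = pos$start - 1L, end = pos$end,
                      system = lab$system, class = lab$class,
                      stringsAsFactors = FALSE)
  patterns <- vapply(cc$classes, canonical_pattern, logical(length(stages)),
                     n_stages = length(stages))
  atac <- lapply(systems, function(s) {
    per_stage <- lapply(seq_along(stages), function(ti) {
      open <- truth$system == s & patterns[ti, truth$class]
      idx <- which(open)
      if (cc$dropout > 0 && length(idx)) {
        idx <- idx[runif(length(idx)) >= cc$dropout]
      }
      if (length(idx) == 0L) {
        gr <- empty_peaks()
      } else {
        st <- pos$start[idx]
        en <- pos$end[idx]
        if (cc$jitter_sd > 0) {
          st <- st + round(rnorm(length(idx), 0, cc$jitter_sd))
          en <- en + round(rnorm(length(idx), 0, cc$jitter_sd))
          en <- pmax(en, st + 50L)  # keep a usable peak width
          st <- pmax(st, 1L)
        }
        gr <- GenomicRanges::GRanges(cc$chrom, IRanges(st, en))
        mcols(gr)$name <- truth$region_id[idx]
        mcols(gr)$score <- rep(0, length(idx))
      }
      sort_peaks(gr)
    })
    names(per_stage) <- stages
    per_stage
  })
  names(atac) <- systems
  list(atac = atac, truth = truth)
}

#' Plant factor-binding peaks
#'
#' Three layers, all recorded in truth tables:
#' * *direct binding*: for each factor and each of its systems, a
#'   `direct_fraction` Bernoulli draw over that system's CO/OC regions
#'   places an exact binding peak on the region (planted direct effect);
#'   unbound CO/OC regions are planted indirect.
#' * *co-binding*: disjoint regions on the binding chromosome realise the
#'   predicted/actual structure — `lost` regions are bound by both factors
#'   in their single-factor systems only, `common` in the single-factor
#'   and the combined system, `gained` by both factors in the combined
#'   system only; single-factor decoy peaks are added to each set.
#' * *promoter binding*: `bound_up`/`bound_down`/`bound_null` genes
#'   (sampled from the planted up, planted down and unplanted genes) get a
#'   peak around their TSS in every binding set of the SALL4 factor.
#'
#' @param cfg a [fixture_config()] list.
#' @param cads_truth truth data.frame from [plant_cads()].
#' @param gene_truth truth data.frame from [plant_gene_truth()].
#' @param model the `GeneModel` from [make_genome_and_genes()].
#' @param seed integer seed.
#' @return list with `binding` (nested `[[factor]][[system]]` `GRanges`),
#'   `region_truth` (cads_truth plus `bound_<factor>` flags), `cobind_truth`
#'   (region role table) and `gene_truth` (input plus `bound` flag).
#' @export
plant_binding <- function(cfg, cads_truth, gene_truth, model, seed = 1L) {
  bc <- cfg$binding
  if (bc$direct_fraction < 0 || bc$direct_fraction > 1) {
    stop("direct_fraction must be in [0, 1]")
  }
  set.seed(seed)
  factors <- names(bc$factors)
  binding <- lapply(factors, function(f) {
    sets <- lapply(bc$factors[[f]], function(s) empty_peaks())
    names(sets) <- bc$factors[[f]]
    sets
  })
  names(binding) <- factors

  region_truth <- cads_truth
  for (f in factors) region_truth[[paste0("bound_", f)]] <- FALSE
  changed <- grepl("^(CO|OC)", cads_truth$class)
  for (f in factors) {
    for (s in bc$factors[[f]]) {
      cand <- which(region_truth$system == s & changed)
      bound <- cand[runif(length(cand)) < bc$direct_fraction]
      region_truth[[paste0("bound_", f)]][bound] <- TRUE
      if (length(bound)) {
        gr <- GenomicRanges::GRanges(region_truth$chrom[bound],
                                     IRanges(region_truth$start[bound] + 1L,
                                             region_truth$end[bound]))
        mcols(gr)$name <- region_truth$region_id[bound]
        mcols(gr)$score <- rep(0, length(bound))
        binding[[f]][[s]] <- suppressWarnings(c(binding[[f]][[s]], gr))
      }
    }
  }

  # co-binding structure on its own chromosome
  roles <- rep(c("lost", "common", "gained"), times = bc$cobind)
  n_decoy <- bc$decoys_per_set * 4L
  n_cb <- length(roles) + n_decoy
  widths <- pmax(150, round(rnorm(n_cb, cfg$cads$peak_width_mean,
                                  cfg$cads$peak_width_sd)))
  gaps <- round(runif(n_cb, cfg$cads$min_gap, cfg$cads$max_gap))
  pos <- layout_intervals(n_cb, widths, gaps, cfg$chromosomes[[bc$chrom]],
                          "co-binding region")
  cb_gr <- GenomicRanges::GRanges(bc$chrom, IRanges(pos$start, pos$end))
  mcols(cb_gr)$name <- sprintf("CB%05d", seq_len(n_cb))
  mcols(cb_gr)$score <- rep(0, n_cb)
  ri <- seq_along(roles)
  cobind_truth <- data.frame(region_id = mcols(cb_gr)$name[ri],
                             chrom = bc$chrom, start = pos$start[ri] - 1L,
                             end = pos$end[ri], role = roles,
                             stringsAsFactors = FALSE)
  single <- cb_gr[which(roles %in% c("lost", "common"))]
  combined <- cb_gr[which(roles %in% c("common", "gained"))]
  decoy <- split(cb_gr[length(roles) + seq_len(n_decoy)],
                 rep(1:4, each = bc$decoys_per_set))
  binding$SALL4$S4 <- suppressWarnings(c(binding$SALL4$S4, single, decoy[[1L]]))
  binding$OCT4$O4 <- suppressWarnings(c(binding$OCT4$O4, single, decoy[[2L]]))
  binding$SALL4$`O+S` <- suppressWarnings(c(binding$SALL4$`O+S`, combined, decoy[[3L]]))
  binding$OCT4$`O+S` <- suppressWarnings(c(binding$OCT4$`O+S`, combined, decoy[[4L]]))

  # promoter binding over planted and null genes (SALL4 sets)
  gene_truth$bound <- FALSE
  up_pool <- gene_truth$gene[!is.na(gene_truth$direction) &
                               gene_truth$direction == "up"]
  down_pool <- gene_truth$gene[!is.na(gene_truth$direction) &
                                 gene_truth$direction == "down"]
  null_pool <- gene_truth$gene[is.na(gene_truth$direction)]
  bound_genes <- c(sample(up_pool, bc$bound_up),
                   sample(down_pool, bc$bound_down),
                   sample(null_pool, bc$bound_null))
  gene_truth$bound[gene_truth$gene %in% bound_genes] <- TRUE
  gi <- match(bound_genes, model$genes$gene_id)
  prom <- GenomicRanges::GRanges(model$genes$chrom[gi],
                                 IRanges(pmax(1L, model$genes$tss[gi] - bc$promoter_halfwidth),
                                         model$genes$tss[gi] + bc$promoter_halfwidth))
  mcols(prom)$name <- bound_genes
  mcols(prom)$score <- rep(0, length(prom))
  for (s in bc$factors$SALL4) {
    binding$SALL4[[s]] <- suppressWarnings(c(binding$SALL4[[s]], prom))
  }

  binding <- lapply(binding, function(x) lapply(x, sort_peaks))
  list(binding = binding, region_truth = region_truth,
       cobind_truth = cobind_truth, gene_truth = gene_truth)
}

#' Plant the gene-level expression truth
#'
#' Samples `genes_per_cluster` genes for each of the 42 (direction x
#' combination x ratio-bin) clusters and assigns baseline, MEF and ESC
#' means realising the planted bin (ESC/MEF of 4, 1 and 1/4 for high, mid,
#' low). Unplanted genes are null (no effect, equal endpoint means).
#'
#' @param cfg a [fixture_config()] list.
#' @param gene_ids character vector of all gene ids (from the gene model).
#' @param seed integer seed.
#' @return data.frame: gene, direction (NA for null), combination, bin,
#'   base_mean, mef_mean, esc_mean.
#' @export
plant_gene_truth <- function(cfg = fixture_config(), gene_ids, seed = 1L) {
  ex <- cfg$expression
  set.seed(seed)
  grid <- expand.grid(direction = c("up", "down"),
                      combination = COMBINATION_ORDER,
                      bin = RATIO_BINS, stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = ex$genes_per_cluster), ]
  n_planted <- nrow(grid)
  if (n_planted > length(gene_ids)) stop("not enough genes to plant clusters")
  planted <- sample(gene_ids, n_planted)
  truth <- data.frame(gene = gene_ids, direction = NA_character_,
                      combination = NA_character_, bin = NA_character_,
                      stringsAsFactors = FALSE)
  pi <- match(planted, truth$gene)
  truth$direction[pi] <- grid$direction
  truth$combination[pi] <- grid$combination
  truth$bin[pi] <- grid$bin
  base <- rlnorm(length(gene_ids), ex$null_meanlog, ex$null_sdlog)
  base[pi] <- rlnorm(n_planted, ex$planted_meanlog, ex$planted_sdlog)
  truth$base_mean <- base
  truth$mef_mean <- base
  ratio <- c(high = 4, mid = 1, low = 0.25)
  truth$esc_mean <- base * ifelse(is.na(truth$bin), 1, ratio[truth$bin])
  truth
}

#' Simulate the count matrix
#'
#' Negative-binomial counts with a gene-constant dispersion and per-sample
#' library factors. Planted genes carry their `effect_lfc` log2 effect (up
#' or down) in every induction stage of every system in their planted
#' combination, relative to the control-system baseline; MEF and ESC
#' reference samples (system `REF`) draw from the planted endpoint means.
#'
#' @param cfg a [fixture_config()] list.
#' @param gene_truth data.frame from [plant_gene_truth()].
#' @param seed integer seed.
#' @return list with `counts` (integer matrix) and `samples` (sample sheet
#'   data.frame: sample, system, stage, replicate, lib_factor).
#' @export
simulate_counts <- function(cfg = fixture_config(), gene_truth, seed = 1L) {
  ex <- cfg$expression
  if (ex$dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  induction <- setdiff(cfg$stages, c("MEF", "ESC"))
  samples <- rbind(
    expand.grid(system = cfg$systems, stage = induction,
                replicate = seq_len(ex$replicates),
                stringsAsFactors = FALSE),
    expand.grid(system = "REF", stage = c("MEF", "ESC"),
                replicate = seq_len(ex$replicates),
                stringsAsFactors = FALSE))
  samples$sample <- paste(gsub("\\+", "p", samples$system),
                          samples$stage, paste0("r", samples$replicate),
                          sep = "_")
  samples <- samples[order(samples$system, samples$stage, samples$replicate), ]
  rownames(samples) <- NULL
  samples$lib_factor <- runif(nrow(samples), ex$lib_range[1], ex$lib_range[2])

  in_combo <- function(sys) {
    !is.na(gene_truth$combination) &
      vapply(strsplit(gene_truth$combination, "/", fixed = TRUE),
             function(x) sys %in% x, TRUE)
  }
  effect <- ifelse(is.na(gene_truth$direction), 0,
                   ifelse(gene_truth$direction == "up",
                          ex$effect_lfc, -ex$effect_lfc))
  mu_for <- function(system, stage) {
    if (system == "REF") {
      if (stage == "MEF") gene_truth$mef_mean else gene_truth$esc_mean
    } else if (system %in% c("S4", "O4", "O+S")) {
      gene_truth$base_mean * ifelse(in_combo(system), 2^effect, 1)
    } else {
      gene_truth$base_mean
    }
  }
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    mu <- mu_for(samples$system[j], samples$stage[j]) * samples$lib_factor[j]
    as.numeric(rnbinom(nrow(gene_truth), mu = mu, size = 1 / ex$dispersion))
  }, numeric(nrow(gene_truth)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_truth$gene, samples$sample)
  list(counts = counts, samples = samples[, c("sample", "system", "stage",
                                              "replicate", "lib_factor")])
}

#' Build the full synthetic fixture
#'
#' Orchestrates genome/gene generation, CADs planting, expression-truth
#' planting, binding planting and count simulation. All randomness flows
#' from `seed` through per-stage sub-seeds (drawn once from the master
#' seed), so each component is independently reproducible.
#'
#' @param cfg a [fixture_config()] list.
#' @param seed master integer seed.
#' @return a `cads_fixture`: list with `config`, `seed`, `model`, `atac`,
#'   `binding`, `counts`, `samples` and `truth` (list `regions`, `cobind`,
#'   `genes`).
#' @export
make_fixture <- function(cfg = fixture_config(), seed = 1L) {
  set.seed(seed)
  sub <- sample.int(2^30, 5L)
  model <- make_genome_and_genes(cfg, seed = sub[1L])
  cads <- plant_cads(cfg, seed = sub[2L])
  gene_truth <- plant_gene_truth(cfg, model$genes$gene_id, seed = sub[3L])
  bind <- plant_binding(cfg, cads$truth, gene_truth, model, seed = sub[4L])
  expr <- simulate_counts(cfg, bind$gene_truth, seed = sub[5L])
  structure(list(config = cfg, seed = seed, model = model,
                 atac = cads$atac, binding = bind$binding,
                 counts = expr$counts, samples = expr$samples,
                 truth = list(regions = bind$region_truth,
                              cobind = bind$cobind_truth,
                              genes = bind$gene_truth)),
            class = "cads_fixture")
}

#' @export
print.cads_fixture <- function(x, ...) {
  cat("cads_fixture (seed", x$seed, "):",
      nrow(x$truth$regions), "planted regions,",
      nrow(x$truth$genes), "genes,",
      ncol(x$counts), "expression samples\n")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits exactly the formats the pipeline consumes: per-sample BED6 ATAC
#' peaks under `atac/`, per-(factor, system) binding peaks under
#' `binding/`, a gene-model TSV, counts and sample-sheet TSVs, the truth
#' tables as JSON, and a ready-to-run `config.yaml`. Re-running with the
#' same fixture is byte-identical.
#'
#' @param fix a `cads_fixture`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(fix, outdir) {
  stopifnot(is(fix, "cads_fixture"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(x) gsub("\\+", "p", x)

  atac_paths <- list()
  for (s in names(fix$atac)) {
    atac_paths[[s]] <- list()
    for (t in names(fix$atac[[s]])) {
      p <- file.path("atac", paste0(safe(s), "_", t, ".bed"))
      write_peaks(fix$atac[[s]][[t]], file.path(outdir, p))
      atac_paths[[s]][[t]] <- p
    }
  }
  binding_paths <- list()
  for (f in names(fix$binding)) {
    binding_paths[[f]] <- list()
    for (s in names(fix$binding[[f]])) {
      p <- file.path("binding", paste0(f, "_", safe(s), ".bed"))
      write_peaks(fix$binding[[f]][[s]], file.path(outdir, p))
      binding_paths[[f]][[s]] <- p
    }
  }

  gm <- fix$model$genes
  ex_by_gene <- split(fix$model$exons, mcols(fix$model$exons)$gene_id)
  ex_by_gene <- ex_by_gene[gm$gene_id]
  gm_out <- data.frame(gene_id = gm$gene_id, chrom = gm$chrom,
                       strand = gm$strand, gene_start = gm$start - 1L,
                       gene_end = gm$end,
                       exon_starts = vapply(ex_by_gene, function(e)
                         paste(GenomicRanges::start(e) - 1L, collapse = ","), ""),
                       exon_ends = vapply(ex_by_gene, function(e)
                         paste(GenomicRanges::end(e), collapse = ","), ""))
  write.table(gm_out, file.path(outdir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  counts_out <- data.frame(gene = rownames(fix$counts), fix$counts,
                           check.names = FALSE)
  write.table(counts_out, file.path(outdir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fix$samples, file.path(outdir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fix$truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)

  config <- list(
    stages = as.list(fix$config$stages),
    systems = as.list(fix$config$systems),
    control_system = "DsRed",
    atac = atac_paths,
    binding = binding_paths,
    gene_model = "genes.tsv",
    counts = "counts.tsv",
    samples = "samples.tsv",
    thresholds = list(min_bp = 1L, gap = 0L, lfc_threshold = 1,
                      alpha = 0.05, pseudocount = 1, promoter_window = 3000L),
    modes = list(strict_monotone = FALSE, single_system_expression = FALSE),
    outdir = "results")
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Score recovery of planted trajectory classes
#'
#' Matches each planted region to the background region it overlaps most
#' and compares the recovered class in the planted system against the
#' planted class.
#'
#' @param assignments named list of `CADsAssignment`s (one per system, on a
#'   shared background).
#' @param truth region truth data.frame (from [plant_cads()] /
#'   [make_fixture()]).
#' @return data.frame: region_id, system, planted, recovered (NA when the
#'   planted region overlaps no background region).
#' @export
evaluate_cads_recovery <- function(assignments, truth) {
  regions <- assignments[[1L]]$regions
  truth_gr <- GenomicRanges::GRanges(truth$chrom,
                                     IRanges(truth$start + 1L, truth$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(truth_gr, regions, ignore.strand = TRUE))
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    truth_gr[queryHits(hits)], regions[subjectHits(hits)]))
  best <- tapply(seq_along(ov), queryHits(hits),
                 function(i) subjectHits(hits)[i][which.max(ov[i])])
  match_idx <- rep(NA_integer_, nrow(truth))
  match_idx[as.integer(names(best))] <- unlist(best)
  recovered <- rep(NA_character_, nrow(truth))
  for (s in unique(truth$system)) {
    ti <- which(truth$system == s & !is.na(match_idx))
    recovered[ti] <- as.character(assignments[[s]]$class[match_idx[ti]])
  }
  data.frame(region_id = truth$region_id, system = truth$system,
             planted = truth$class, recovered = recovered,
             stringsAsFactors = FALSE)
}
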