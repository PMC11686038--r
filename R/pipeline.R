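# Config-driven orchestration: validate a declarative YAML config, run the
# stages (background -> occupancy -> trajectory classes -> comparisons and
# synergy patterns -> binding integration -> expression classification) and
# write a deterministic report bundle.

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes an equivalent list), checks required keys,
#' threshold ranges and that every referenced input path exists, and
#' reports *all* failures at once. Relative paths are resolved against the
#' config file's directory.
#'
#' @param config path to a YAML file, or a config list.
#' @param base_dir directory against which relative paths are resolved
#'   (default: the config file's directory, or `"."` for a list).
#' @return the validated config list (paths resolved, defaults filled),
#'   with class `PipelineConfig`.
#' @export
validate_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  errors <- character(0)
  need <- c("stages", "systems", "control_system", "atac")
  for (k in need) {
    if (is.null(config[[k]])) errors <- c(errors, paste0("missing key: ", k))
  }
  if (length(errors) == 0L) {
    config$stages <- unlist(config$stages)
    config$systems <- unlist(config$systems)
    if (length(config$stages) < 3L) {
      errors <- c(errors, "stage axis must have >= 3 stages")
    }
    resolve <- function(p) {
      ifelse(file.exists(p), p, file.path(base_dir, p))
    }
    for (s in config$systems) {
      for (t in config$stages) {
        p <- config$atac[[s]][[t]]
        if (is.null(p)) {
          errors <- c(errors, paste0("missing atac peak file for (", s, ", ", t, ")"))
        } else {
          config$atac[[s]][[t]] <- resolve(p)
          if (!file.exists(config$atac[[s]][[t]])) {
            errors <- c(errors, paste0("atac file not found: ", p))
          }
        }
      }
    }
    for (f in names(config$binding)) {
      for (s in names(config$binding[[f]])) {
        config$binding[[f]][[s]] <- resolve(config$binding[[f]][[s]])
        if (!file.exists(config$binding[[f]][[s]])) {
          errors <- c(errors, paste0("binding file not found: ", f, "/", s))
        }
      }
    }
    for (k in c("gene_model", "counts", "samples")) {
      if (!is.null(config[[k]])) {
        config[[k]] <- resolve(config[[k]])
        if (!file.exists(config[[k]])) {
          errors <- c(errors, paste0(k, " file not found: ", config[[k]]))
        }
      }
    }
    th_defaults <- list(min_bp = 1L, gap = 0L, lfc_threshold = 1,
                        alpha = 0.05, pseudocount = 1, promoter_window = 3000L)
    config$thresholds <- modifyList(th_defaults, config$thresholds %||% list())
    th <- config$thresholds
    if (th$min_bp < 1) errors <- c(errors, "thresholds$min_bp must be >= 1")
    if (th$gap < 0) errors <- c(errors, "thresholds$gap must be >= 0")
    if (th$alpha <= 0 || th$alpha > 1) {
      errors <- c(errors, "thresholds$alpha must be in (0, 1]")
    }
    if (th$lfc_threshold < 0) {
      errors <- c(errors, "thresholds$lfc_threshold must be >= 0")
    }
    md_defaults <- list(strict_monotone = FALSE,
                        single_system_expression = FALSE)
    config$modes <- modifyList(md_defaults, config$modes %||% list())
    if (!config$control_system %in% config$systems) {
      errors <- c(errors, "control_system must be one of systems")
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "))
  }
  structure(config, class = "PipelineConfig")
}

stage_log <- function(stage, ...) {
  message("[", format(Sys.time(), "%H:%M:%S"), "] ", stage, ": ", ...)
}

#' Run the full pipeline
#'
#' Executes, in order: integrated background construction, per-system
#' occupancy and trajectory classification, cross-system comparisons
#' (treatment vs control over CO1-4, OC1-4, PO scopes) and, when the three
#' systems S4/O4/O+S are present, the synergy-pattern partition; binding
#' integration (effect classes per factor x system, predicted vs actual
#' co-binding when both factors cover both single systems and the combined
#' system, promoter fractions, binding x DE gene overlap); expression
#' normalisation, per-stage DE calls vs the control system, both-direction
#' exclusion, cross-system (or single-system) cluster assembly and
#' within-cluster ranking. Outputs are deterministic: re-running on the
#' same inputs reproduces identical files.
#'
#' @param config a `PipelineConfig`, a config list or a YAML path (passed
#'   through [validate_config()]).
#' @param outdir output directory (default: the config's `outdir`, resolved
#'   against the working directory).
#' @return a `ReportBundle` list (tables and result objects), invisibly
#'   written as TSV/JSON/BED under `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!is(config, "PipelineConfig")) config <- validate_config(config)
  outdir <- outdir %||% config$outdir %||% "results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  stages <- config$stages
  systems <- config$systems
  bundle <- list(config = config)

  stage_log("atac", "reading peak files for ", length(systems), " systems")
  atac <- lapply(systems, function(s) {
    st <- lapply(stages, function(t) read_peaks(config$atac[[s]][[t]]))
    names(st) <- stages
    st
  })
  names(atac) <- systems

  stage_log("background", "merging all samples")
  background <- build_background(unlist(atac, recursive = FALSE), gap = th$gap)
  stage_log("background", length(background), " regions")

  occ <- compute_occupancy(background, atac, stages = stages,
                           min_bp = th$min_bp)
  mode <- if (isTRUE(config$modes$strict_monotone)) "strict_monotone"
          else "earliest_permanent"
  assignments <- lapply(systems, function(s) classify_system(occ, s, mode = mode))
  names(assignments) <- systems
  counts_tab <- vapply(assignments, function(a) as.integer(a$counts),
                       integer(length(trajectory_classes(length(stages)))))
  rownames(counts_tab) <- trajectory_classes(length(stages))
  stopifnot(all(colSums(counts_tab) == length(background)))  # cross-foot
  write.table(data.frame(class = rownames(counts_tab), counts_tab,
                         check.names = FALSE),
              file.path(outdir, "cads_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in systems) {
    a <- assignments[[s]]
    for (cl in levels(a$class)) {
      idx <- which(a$class == cl)
      if (length(idx)) {
        write_peaks(background[idx],
                    file.path(outdir, "cads",
                              paste0(gsub("\\+", "p", s), ".", cl, ".bed")))
      }
    }
  }
  bundle$assignments <- assignments
  bundle$cads_counts <- counts_tab
  stage_log("cads", "classified ", length(background), " regions x ",
            length(systems), " systems")

  scopes <- list(CO = paste0("CO", 1:4), OC = paste0("OC", 1:4), PO = "PO")
  comp_rows <- list()
  for (s in setdiff(systems, config$control_system)) {
    for (sc in names(scopes)) {
      cmp <- compare_systems(assignments[[s]],
                             assignments[[config$control_system]],
                             scopes[[sc]])
      comp_rows[[paste(s, sc)]] <- data.frame(
        system = s, control = config$control_system, scope = sc,
        common = cmp$counts[["common"]],
        system_specific = cmp$counts[["specific_a"]],
        control_specific = cmp$counts[["specific_b"]])
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  rownames(comparisons) <- NULL
  write.table(comparisons, file.path(outdir, "system_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$comparisons <- comparisons

  if (all(c("O+S", "S4", "O4") %in% systems)) {
    syn <- synergy_patterns(assignments[["O+S"]], assignments[["S4"]],
                            assignments[["O4"]])
    write.table(syn$counts, file.path(outdir, "synergy_patterns.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$synergy <- syn
    stage_log("synergy", "partitioned O+S transitions")
  }

  model <- NULL
  if (!is.null(config$gene_model)) model <- read_gene_model(config$gene_model)

  if (length(config$binding)) {
    binding <- lapply(config$binding, function(x) lapply(x, read_peaks))
    effect_rows <- list()
    for (f in names(binding)) {
      for (s in names(binding[[f]])) {
        if (!s %in% systems) next
        eff <- classify_effects(assignments[[s]], binding[[f]][[s]],
                                min_bp = th$min_bp)
        effect_rows[[paste(f, s)]] <- data.frame(
          factor = f, system = s, t(as.integer(eff$counts)))
        names(effect_rows[[paste(f, s)]])[-(1:2)] <- EFFECT_CLASSES
      }
    }
    effects <- do.call(rbind, effect_rows)
    rownames(effects) <- NULL
    write.table(effects, file.path(outdir, "effect_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$effects <- effects
    stage_log("binding", "effect classes for ", nrow(effects),
              " (factor, system) pairs")

    fs <- names(binding)
    if (length(fs) == 2L) {
      f1 <- fs[1L]; f2 <- fs[2L]
      s1 <- setdiff(names(binding[[f1]]), "O+S")[1L]
      s2 <- setdiff(names(binding[[f2]]), "O+S")[1L]
      have_combined <- "O+S" %in% names(binding[[f1]]) &&
        "O+S" %in% names(binding[[f2]])
      if (!is.na(s1) && !is.na(s2) && have_combined) {
        predicted <- predicted_cobinding(binding[[f1]][[s1]],
                                         binding[[f2]][[s2]],
                                         min_bp = th$min_bp)
        actual <- predicted_cobinding(binding[[f1]][["O+S"]],
                                      binding[[f2]][["O+S"]],
                                      min_bp = th$min_bp)
        cb <- compare_predicted_actual(predicted, actual, min_bp = th$min_bp)
        write_peaks(cb$predicted, file.path(outdir, "cobinding", "predicted.bed"))
        write_peaks(cb$actual, file.path(outdir, "cobinding", "actual.bed"))
        write_peaks(cb$lost, file.path(outdir, "cobinding", "lost.bed"))
        write_peaks(cb$gained, file.path(outdir, "cobinding", "gained.bed"))
        cb_report <- as.list(cb$counts)
        if (!is.null(model)) {
          cb_report$promoter_fraction_lost <-
            if (length(cb$lost)) promoter_fraction(cb$lost, model) else NA
          cb_report$promoter_fraction_gained <-
            if (length(cb$gained)) promoter_fraction(cb$gained, model) else NA
        }
        jsonlite::write_json(cb_report, file.path(outdir, "cobinding.json"),
                             auto_unbox = TRUE, digits = NA)
        bundle$cobinding <- cb
        stage_log("cobinding", "predicted ", length(predicted),
                  ", actual ", length(actual))
      }
    }
    bundle$binding <- binding
  }

  if (!is.null(config$counts) && !is.null(config$samples)) {
    cnt <- read.table(config$counts, header = TRUE, sep = "\t",
                      check.names = FALSE, row.names = 1L)
    cnt <- as.matrix(cnt)
    samples <- read.table(config$samples, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    em <- normalize_counts(expression_matrix(cnt, samples))
    induction <- intersect(stages, unique(em$samples$stage))
    induction <- setdiff(induction, c("MEF", "ESC"))
    de_systems <- if (isTRUE(config$modes$single_system_expression)) {
      setdiff(systems, config$control_system)[1L]
    } else {
      intersect(c("S4", "O4", "O+S"), unique(em$samples$system))
    }
    de <- do.call(rbind, lapply(de_systems, function(s) {
      do.call(rbind, lapply(induction, function(t) {
        call_de(em, s, t, config$control_system,
                lfc_threshold = th$lfc_threshold, alpha = th$alpha)
      }))
    }))
    sets <- lapply(de_systems, function(s) integrate_system_de(de, s))
    names(sets) <- de_systems
    mef_cols <- which(em$samples$stage == "MEF")
    esc_cols <- which(em$samples$stage == "ESC")
    bins <- bin_by_endpoint_ratio(rowMeans(em$counts[, esc_cols, drop = FALSE]),
                                  rowMeans(em$counts[, mef_cols, drop = FALSE]),
                                  pseudocount = th$pseudocount)
    names(bins) <- rownames(em$counts)
    single <- isTRUE(config$modes$single_system_expression)
    clusters <- do.call(rbind, lapply(c("up", "down"), function(d) {
      combos <- if (single) {
        s <- de_systems[1L]
        data.frame(gene = sets[[s]][[d]], combination = s,
                   stringsAsFactors = FALSE)
      } else {
        classify_cross_system(sets, d)
      }
      cl <- assemble_clusters(combos, bins, direction = d,
                              mode = if (single) "single_system" else "cross_system")
      rank_sys <- if (single) de_systems[1L] else "O+S"
      if (!rank_sys %in% em$samples$system) rank_sys <- de_systems[1L]
      do.call(rbind, lapply(split(cl, cl$label), function(cc) {
        rk <- rank_within_cluster(cc$gene, em, rank_sys, direction = d,
                                  stages = induction)
        cc <- cc[match(rk$gene, cc$gene), ]
        cc$rank <- rk$rank
        cc$peak_stage <- rk$peak_stage
        cc
      }))
    }))
    if (is.null(clusters)) {
      clusters <- data.frame(gene = character(0), direction = character(0),
                             combination = character(0), bin = character(0),
                             label = character(0), rank = integer(0),
                             peak_stage = character(0))
    }
    rownames(clusters) <- NULL
    clusters <- clusters[order(clusters$direction, clusters$label,
                               clusters$rank), ]
    write.table(clusters, file.path(outdir, "expression_clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$de <- de
    bundle$direction_sets <- sets
    bundle$clusters <- clusters
    stage_log("expression", nrow(clusters), " clustered genes")

    if (!is.null(model) && !is.null(bundle$binding)) {
      f1 <- names(bundle$binding)[1L]
      s1 <- names(bundle$binding[[f1]])[1L]
      ann <- annotate_to_genes(bundle$binding[[f1]][[s1]], model,
                               promoter_window = th$promoter_window)
      bound_genes <- unique(ann$gene_id[!is.na(ann$gene_id) &
                                          grepl("^promoter", ann$category)])
      ov_sys <- intersect(s1, de_systems)
      ov_set <- if (length(ov_sys)) sets[[ov_sys[1L]]] else sets[[1L]]
      ov <- intersect_binding_de(bound_genes, ov_set)
      jsonlite::write_json(as.list(ov$counts),
                           file.path(outdir, "binding_de_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      bundle$binding_de <- ov
    }
  }

  meta <- list(package = "cadsr",
               version = as.character(utils::packageVersion("cadsr")),
               n_background_regions = length(background),
               systems = systems, stages = stages,
               thresholds = th)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(bundle) <- "ReportBundle"
  invisible(bundle)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}
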