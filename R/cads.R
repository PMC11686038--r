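# Chromatin accessibility dynamics (CADs): integrated background, per-stage
# occupancy, trajectory classification, cross-system comparison and synergy
# patterns.

#' Build the integrated peak background
#'
#' Merges the peaks of every sample of every system (including the MEF and
#' ESC references) into one sorted, non-overlapping region set — the
#' universe on which occupancy and trajectory classes are evaluated.
#'
#' @param all_peak_sets list of `GRanges` (one per sample).
#' @param gap merge gap in bp (see [merge_intervals()]).
#' @return sorted non-overlapping `GRanges`.
#' @export
build_background <- function(all_peak_sets, gap = 0L) {
  stopifnot(is.list(all_peak_sets), length(all_peak_sets) >= 1L)
  if (all(vapply(all_peak_sets, length, 0L) == 0L)) {
    stop("all input peak sets are empty")
  }
  pooled <- suppressWarnings(
    do.call(c, lapply(unname(all_peak_sets), GenomicRanges::granges)))
  merge_intervals(pooled, gap = gap)
}

#' Per-stage occupancy of background regions
#'
#' A background region is called open in sample (system, stage) when it
#' shares at least `min_bp` bases with some peak of that sample.
#'
#' @param background `GRanges` from [build_background()].
#' @param system_peaks nested list: `system_peaks[[system]][[stage]]` is the
#'   `GRanges` of that sample. Every system must provide every stage.
#' @param stages ordered stage axis; first entry is the start reference
#'   (MEF), last the end reference (ESC).
#' @param min_bp minimum overlap in bp.
#' @return an `OccupancyMatrix`: list with `regions`, `stages`, `systems`,
#'   and `open` (per system, a logical regions x stages matrix).
#' @export
compute_occupancy <- function(background, system_peaks,
                              stages = DEFAULT_STAGES, min_bp = 1L) {
  stopifnot(length(stages) >= 3L, length(background) >= 1L)
  systems <- names(system_peaks)
  if (is.null(systems) || any(!nzchar(systems))) {
    stop("system_peaks must be a named list keyed by system")
  }
  missing <- unlist(lapply(systems, function(s) {
    mis <- setdiff(stages, names(system_peaks[[s]]))
    if (length(mis)) paste0(s, ":", mis) else character(0)
  }))
  if (length(missing)) {
    stop("missing (system, stage) peak sets: ", paste(missing, collapse = ", "))
  }
  open <- lapply(systems, function(s) {
    m <- vapply(stages, function(t) {
      peak_overlaps(background, system_peaks[[s]][[t]], min_bp = min_bp)
    }, logical(length(background)))
    dimnames(m) <- list(NULL, stages)
    m
  })
  names(open) <- systems
  structure(list(regions = background, stages = stages,
                 systems = systems, open = open),
            class = "OccupancyMatrix")
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat("OccupancyMatrix:", length(x$regions), "regions x",
      length(x$stages), "stages x", length(x$systems), "systems\n")
  invisible(x)
}

#' Classify one occupancy pattern
#'
#' Assigns a trajectory class to an ordered open/closed pattern over the
#' stage axis. With start state `s` (first stage) and end state `e` (last):
#' * `s = closed, e = open`: `CO_k`, where k indexes (1-based, among
#'   non-start stages) the earliest stage from which the region stays open
#'   through the end — `CO1` is closed at MEF and permanently open from D0
#'   onwards; `CO5` opens only at ESC.
#' * `s = open, e = closed`: `OC_k`, symmetric (earliest stage from which
#'   permanently closed).
#' * `s = open, e = open`: `PO` when open at every stage, else `PO_UNSTABLE`.
#' * `s = closed, e = closed`: `TRANSIENT` when open somewhere, else
#'   `NEVER_OPEN`.
#'
#' With `mode = "strict_monotone"`, `CO_k`/`OC_k` are only assigned to
#' patterns with a single transition (closed^k then open, or the reverse);
#' other changed patterns fall into `TRANSIENT`.
#'
#' @param pattern logical (or 0/1) vector over the stage axis, length >= 3.
#' @param mode `"earliest_permanent"` (default) or `"strict_monotone"`.
#' @return class label (character scalar).
#' @export
classify_trajectory <- function(pattern,
                                mode = c("earliest_permanent", "strict_monotone")) {
  if (length(pattern) < 3L || anyNA(pattern)) {
    stop("pattern must be a complete occupancy vector over >= 3 stages")
  }
  classify_patterns(matrix(as.logical(pattern), nrow = 1L), mode = mode)[1L]
}

#' Classify occupancy patterns (vectorised)
#'
#' @param m logical matrix, regions x stages.
#' @inheritParams classify_trajectory
#' @return character vector of class labels, one per row.
#' @export
classify_patterns <- function(m,
                              mode = c("earliest_permanent", "strict_monotone")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m), ncol(m) >= 3L, !anyNA(m))
  storage.mode(m) <- "logical"
  n <- ncol(m)
  s <- m[, 1L]
  e <- m[, n]
  # last closed / last open stage index (0 when none)
  last_closed <- Reduce(pmax, lapply(seq_len(n), function(j) ifelse(m[, j], 0L, j)))
  last_open <- Reduce(pmax, lapply(seq_len(n), function(j) ifelse(m[, j], j, 0L)))
  n_open <- rowSums(m)
  out <- character(nrow(m))
  co <- !s & e
  oc <- s & !e
  out[co] <- paste0("CO", last_closed[co])
  out[oc] <- paste0("OC", last_open[oc])
  out[s & e] <- ifelse(n_open[s & e] == n, "PO", "PO_UNSTABLE")
  out[!s & !e] <- ifelse(n_open[!s & !e] > 0L, "TRANSIENT", "NEVER_OPEN")
  if (mode == "strict_monotone") {
    # monotone CO: all open stages form the suffix; monotone OC: the prefix
    nonmono_co <- co & (n_open != n - last_closed)
    nonmono_oc <- oc & (n_open != last_open)
    out[nonmono_co | nonmono_oc] <- "TRANSIENT"
  }
  out
}

#' Trajectory classes for one system
#'
#' Applies [classify_patterns()] to every background region's occupancy row
#' in the given system.
#'
#' @param occupancy an `OccupancyMatrix`.
#' @param system system id present in the matrix.
#' @inheritParams classify_trajectory
#' @return a `CADsAssignment`: list with `system`, `regions`, `class`
#'   (factor over [trajectory_classes()]) and `counts` (per-class table).
#' @export
classify_system <- function(occupancy, system,
                            mode = c("earliest_permanent", "strict_monotone")) {
  stopifnot(is(occupancy, "OccupancyMatrix"))
  if (!system %in% occupancy$systems) stop("unknown system: ", system)
  lv <- trajectory_classes(length(occupancy$stages))
  cls <- factor(classify_patterns(occupancy$open[[system]], mode = mode),
                levels = lv)
  structure(list(system = system, regions = occupancy$regions,
                 stages = occupancy$stages, class = cls,
                 counts = table(cls)),
            class = "CADsAssignment")
}

#' @export
print.CADsAssignment <- function(x, ...) {
  cat("CADsAssignment for system", x$system, "-", length(x$regions), "regions\n")
  print(x$counts)
  invisible(x)
}

same_background <- function(a, b) {
  length(a$regions) == length(b$regions) &&
    identical(as.character(GenomicRanges::seqnames(a$regions)),
              as.character(GenomicRanges::seqnames(b$regions))) &&
    identical(GenomicRanges::start(a$regions), GenomicRanges::start(b$regions)) &&
    identical(GenomicRanges::end(a$regions), GenomicRanges::end(b$regions))
}

#' Compare two systems over a class scope
#'
#' Region-level Venn between two CADs assignments on the same background:
#' `common` regions carry a scope class in both systems, `specific_a`/`b`
#' in exactly one. The figure-style three-way comparison (CO1-4, OC1-4, PO)
#' is obtained by calling this once per scope.
#'
#' @param a,b `CADsAssignment`s on the same background.
#' @param class_scope character vector of class labels, e.g.
#'   `paste0("CO", 1:4)`.
#' @return a `SystemComparison`: list with integer region index vectors
#'   `common`, `specific_a`, `specific_b` and a `counts` vector.
#' @export
compare_systems <- function(a, b, class_scope) {
  stopifnot(is(a, "CADsAssignment"), is(b, "CADsAssignment"))
  if (!same_background(a, b)) stop("assignments are not on the same background")
  in_a <- a$class %in% class_scope
  in_b <- b$class %in% class_scope
  structure(list(systems = c(a$system, b$system), scope = class_scope,
                 common = which(in_a & in_b),
                 specific_a = which(in_a & !in_b),
                 specific_b = which(!in_a & in_b),
                 counts = c(common = sum(in_a & in_b),
                            specific_a = sum(in_a & !in_b),
                            specific_b = sum(!in_a & in_b))),
            class = "SystemComparison")
}

#' @export
print.SystemComparison <- function(x, ...) {
  cat("SystemComparison", x$systems[1], "vs", x$systems[2],
      "| scope:", paste(x$scope, collapse = ","), "\n")
  print(x$counts)
  invisible(x)
}

#' Cooperative synergy patterns of the combined system
#'
#' Partitions the regions opened (resp. closed) in the combined O+S system
#' by which single-factor system shares the change. With `CO(x)` the regions
#' of system `x` in the open-direction scope classes (default CO1-CO4) and
#' `OC(x)` likewise for close:
#' * `O+S/S4-C-O` = `CO(os) & CO(s4) & !CO(o4)` (common open with SALL4)
#' * `O+S/O4-C-O` = `CO(os) & CO(o4) & !CO(s4)` (common open with OCT4)
#' * `O+S-S-O`    = `CO(os) & !CO(s4) & !CO(o4)` (open only in O+S)
#' * all-three    = `CO(os) & CO(s4) & CO(o4)`
#' and the four symmetric close-direction sets. Within a direction the four
#' sets are disjoint and their union is the O+S scope set.
#'
#' @param os,s4,o4 `CADsAssignment`s for the combined and the two
#'   single-factor systems, on one background.
#' @param open_scope,close_scope class labels counted as "open" / "close"
#'   transitions (defaults CO1-4 and OC1-4, the successfully transitioning
#'   subgroups).
#' @return a `SynergyPatternSet`: per direction, named integer index sets,
#'   plus a `counts` data.frame.
#' @export
synergy_patterns <- function(os, s4, o4,
                             open_scope = paste0("CO", 1:4),
                             close_scope = paste0("OC", 1:4)) {
  stopifnot(is(os, "CADsAssignment"), is(s4, "CADsAssignment"),
            is(o4, "CADsAssignment"))
  if (!same_background(os, s4) || !same_background(os, o4)) {
    stop("assignments are not on the same background")
  }
  part <- function(scope) {
    in_os <- os$class %in% scope
    in_s4 <- s4$class %in% scope
    in_o4 <- o4$class %in% scope
    list(with_s4 = which(in_os & in_s4 & !in_o4),
         with_o4 = which(in_os & in_o4 & !in_s4),
         os_only = which(in_os & !in_s4 & !in_o4),
         all_three = which(in_os & in_s4 & in_o4))
  }
  open <- part(open_scope)
  close <- part(close_scope)
  counts <- data.frame(
    pattern = c("O+S/S4-C-O", "O+S/O4-C-O", "O+S-S-O", "all-three-open",
                "O+S/S4-C-C", "O+S/O4-C-C", "O+S-S-C", "all-three-close"),
    n = c(lengths(open), lengths(close)))
  structure(list(open = open, close = close, counts = counts,
                 regions = os$regions),
            class = "SynergyPatternSet")
}

#' @export
print.SynergyPatternSet <- function(x, ...) {
  cat("SynergyPatternSet\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Remove peaks overlapping a control sample
#'
#' Whole-peak exclusion: system peaks sharing at least `min_bp` bases with
#' any control peak are dropped (the control acts as a background to
#' subtract, e.g. the same-day DsRed sample).
#'
#' @param system_day_peaks,control_day_peaks `GRanges`.
#' @param min_bp minimum overlap in bp.
#' @return filtered `GRanges`.
#' @export
subtract_control <- function(system_day_peaks, control_day_peaks, min_bp = 1L) {
  if (length(control_day_peaks) == 0L) return(system_day_peaks)
  system_day_peaks[!peak_overlaps(system_day_peaks, control_day_peaks,
                                  min_bp = min_bp)]
}
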