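# Integration of factor-binding (CUT&Tag) peaks with CADs assignments and
# differential-expression gene sets: direct/indirect effects, predicted vs
# actual co-binding, binding x ATAC partitions, binding x DE overlaps.

EFFECT_CLASSES <- c("direct_open", "direct_close", "indirect_open",
                    "indirect_close", "bound_static", "unbound_static")

#' Partition binding peaks against an ATAC peak set
#'
#' @param binding `GRanges` of factor-binding peaks.
#' @param atac `GRanges` of ATAC peaks/regions.
#' @param min_bp minimum overlap in bp.
#' @return list of `GRanges`: `shared` (binding peaks overlapping ATAC),
#'   `binding_only` (the remainder), `atac_only` (ATAC regions with no
#'   binding overlap), plus a `counts` vector.
#' @export
partition_binding_vs_atac <- function(binding, atac, min_bp = 1L) {
  hit_b <- peak_overlaps(binding, atac, min_bp = min_bp)
  hit_a <- peak_overlaps(atac, binding, min_bp = min_bp)
  list(shared = binding[hit_b],
       binding_only = binding[!hit_b],
       atac_only = atac[!hit_a],
       counts = c(shared = sum(hit_b), binding_only = sum(!hit_b),
                  atac_only = sum(!hit_a)))
}

#' Direct/indirect effect classification
#'
#' Crosses each background region's trajectory class with whether the
#' factor binds it (day-0 binding evidence by default): regions that close
#' (OC1-5) are `direct_close` when bound and `indirect_close` otherwise —
#' the factor binds an initially open region that then closes; regions that
#' open (CO1-5) are `direct_open`/`indirect_open`; all remaining regions
#' (PO and residual classes) are `bound_static`/`unbound_static`.
#'
#' @param cads a `CADsAssignment`.
#' @param binding `GRanges` of the factor's binding peaks (one stage; pass
#'   the union of stages for a multi-stage notion of "bound").
#' @param min_bp minimum overlap in bp.
#' @return an `EffectClassification`: list with `effect` (factor over the
#'   six classes along the background) and `counts`.
#' @export
classify_effects <- function(cads, binding, min_bp = 1L) {
  stopifnot(is(cads, "CADsAssignment"))
  bound <- peak_overlaps(cads$regions, binding, min_bp = min_bp)
  n_stage <- length(cads$stages)
  co <- cads$class %in% paste0("CO", seq_len(n_stage - 1L))
  oc <- cads$class %in% paste0("OC", seq_len(n_stage - 1L))
  eff <- rep("unbound_static", length(cads$regions))
  eff[co & bound] <- "direct_open"
  eff[co & !bound] <- "indirect_open"
  eff[oc & bound] <- "direct_close"
  eff[oc & !bound] <- "indirect_close"
  eff[!co & !oc & bound] <- "bound_static"
  eff <- factor(eff, levels = EFFECT_CLASSES)
  structure(list(system = cads$system, effect = eff, bound = bound,
                 class = cads$class, regions = cads$regions,
                 counts = table(eff)),
            class = "EffectClassification")
}

#' @export
print.EffectClassification <- function(x, ...) {
  cat("EffectClassification for system", x$system, "\n")
  print(x$counts)
  invisible(x)
}

#' Predicted co-binding regions of two factors
#'
#' Regions where a peak of factor A and a peak of factor B overlap by at
#' least `min_bp` bases, reported as merged overlap regions (the pairwise
#' intersections, merged). Applied to the two single-factor systems this
#' yields the *predicted* co-occupancy set; applied to the two factors'
#' peaks within the combined system, the *actual* one.
#'
#' @param bind_a,bind_b `GRanges` of the two factors' peaks.
#' @param min_bp minimum overlap in bp.
#' @return merged `GRanges` of co-bound regions.
#' @export
predicted_cobinding <- function(bind_a, bind_b, min_bp = 1L) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(bind_a, bind_b, minoverlap = min_bp,
                                ignore.strand = TRUE))
  if (length(hits) == 0L) return(GenomicRanges::GRanges())
  pieces <- GenomicRanges::pintersect(
    GenomicRanges::granges(bind_a)[queryHits(hits)],
    GenomicRanges::granges(bind_b)[subjectHits(hits)],
    ignore.strand = TRUE)
  merge_intervals(pieces, gap = 0L)
}

#' Compare predicted and actual co-binding sets
#'
#' `lost` are predicted regions with no overlap in the actual set, `gained`
#' are actual regions with no overlap in the predicted set; the common count
#' is counted once per actual region, so `n_actual = n_common + n_gained`
#' and `n_predicted = n_predicted_hit + n_lost` hold exactly.
#'
#' @param predicted,actual `GRanges` co-binding region sets.
#' @param min_bp minimum overlap in bp.
#' @return a `CoBindingComparison`: list with `predicted`, `actual`, `lost`,
#'   `gained` (`GRanges`) and a `counts` vector (`predicted`, `actual`,
#'   `common`, `lost`, `gained`).
#' @export
compare_predicted_actual <- function(predicted, actual, min_bp = 1L) {
  lost <- predicted[!peak_overlaps(predicted, actual, min_bp = min_bp)]
  hit_actual <- peak_overlaps(actual, predicted, min_bp = min_bp)
  gained <- actual[!hit_actual]
  structure(list(predicted = predicted, actual = actual,
                 lost = lost, gained = gained,
                 counts = c(predicted = length(predicted),
                            actual = length(actual),
                            common = sum(hit_actual),
                            lost = length(lost),
                            gained = length(gained))),
            class = "CoBindingComparison")
}

#' @export
print.CoBindingComparison <- function(x, ...) {
  cat("CoBindingComparison\n")
  print(x$counts)
  invisible(x)
}

#' Fraction of peaks near a promoter
#'
#' The fraction of peaks whose midpoint lies within `max_dist` bp of any
#' transcription start site.
#'
#' @param peaks non-empty `GRanges`.
#' @param model a `GeneModel`.
#' @param max_dist distance bound in bp (default 1000, the "<= 1 kb"
#'   promoter-proximal criterion).
#' @return fraction in `[0, 1]`.
#' @export
promoter_fraction <- function(peaks, model, max_dist = 1000L) {
  stopifnot(is(model, "GeneModel"))
  if (length(peaks) == 0L) stop("empty peak set")
  nt <- nearest_tss(as.character(GenomicRanges::seqnames(peaks)),
                    peak_midpoints(peaks), model)
  mean(!is.na(nt$distance) & abs(nt$distance) <= max_dist)
}

#' Overlap bound genes with differential-expression direction sets
#'
#' @param bound_genes character vector of gene ids with binding evidence
#'   (e.g. genes assigned to binding peaks by [annotate_to_genes()]).
#' @param sets a `SystemDirectionSets`.
#' @return a `BindingExpressionOverlap`: list with `bound`, `overlap_up`,
#'   `overlap_down` gene vectors and a `counts` vector (`bound`, `up`,
#'   `down`, `overlap_up`, `overlap_down`, `overlap_total`).
#' @export
intersect_binding_de <- function(bound_genes, sets) {
  stopifnot(is(sets, "SystemDirectionSets"))
  bound <- sort(unique(bound_genes))
  ou <- intersect(bound, sets$up)
  od <- intersect(bound, sets$down)
  structure(list(bound = bound, overlap_up = ou, overlap_down = od,
                 counts = c(bound = length(bound), up = length(sets$up),
                            down = length(sets$down),
                            overlap_up = length(ou),
                            overlap_down = length(od),
                            overlap_total = length(ou) + length(od))),
            class = "BindingExpressionOverlap")
}

#' @export
print.BindingExpressionOverlap <- function(x, ...) {
  cat("BindingExpressionOverlap\n")
  print(x$counts)
  invisible(x)
}
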