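## Post-association artifact screens. Four exclusion criteria are
## applied to significant CNVRs — telomere/centromere proximity, the
## "peninsula" pattern at the variably truncated edge of a common CNV,
## extreme GC content, and recurrent bias samples — plus a probe-density
## screen. Filters flag regions; they never delete them, so the audit
## trail is non-destructive and re-application is idempotent.

#' CNVR filter parameters
#'
#' The underlying criteria are qualitative; every number here is an
#' explicit operationalisation with a configurable default.
#'
#' @param gc_low,gc_high span-mean GC fractions outside `(gc_low,
#'   gc_high)` flag `gc_extreme` (hybridisation bias).
#' @param min_probe_density minimum probes per 100 kb over the span;
#'   below it the region is flagged `low_coverage`.
#' @param peninsula_extension_probes a contributing call "extends" when
#'   it covers at least this many non-significant flanking probes beyond
#'   a region boundary.
#' @param peninsula_fraction flag `peninsula` when at least this
#'   fraction of contributing calls extends.
#' @param max_cnvrs_per_sample a sample contributing to more than this
#'   many significant regions is a bias sample.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(gc_low = 0.25, gc_high = 0.75,
                          min_probe_density = 1.0,
                          peninsula_extension_probes = 5L,
                          peninsula_fraction = 0.5,
                          max_cnvrs_per_sample = 3L) {
  stopifnot(gc_low < gc_high, gc_low > 0, gc_high < 1,
            min_probe_density > 0, peninsula_extension_probes >= 1,
            peninsula_fraction > 0, peninsula_fraction <= 1,
            max_cnvrs_per_sample >= 1)
  structure(list(gc_low = gc_low, gc_high = gc_high,
                 min_probe_density = min_probe_density,
                 peninsula_extension_probes =
                   as.integer(peninsula_extension_probes),
                 peninsula_fraction = peninsula_fraction,
                 max_cnvrs_per_sample = as.integer(max_cnvrs_per_sample)),
            class = "filter_params")
}

## internal: merge flag vectors into the comma-separated filter_flags col
merge_flags <- function(...) {
  sets <- list(...)
  n <- length(sets[[1]])
  vapply(seq_len(n), function(i) {
    f <- sort(unique(unlist(lapply(sets, `[[`, i))))
    paste(f[nzchar(f)], collapse = ",")
  }, "")
}

#' Flag CNVRs on telomere/centromere-proximal cytobands
#'
#' @param cnvrs CNVR data frame.
#' @param exclusion_track interval track of excluded cytobands (role
#'   `exclusion_region`); any 1-bp overlap flags the region.
#' @return list (one element per CNVR) of flag character vectors.
#' @export
flag_positional_exclusions <- function(cnvrs, exclusion_track) {
  flags <- rep(list(character(0)), nrow(cnvrs))
  if (is.null(exclusion_track) || nrow(exclusion_track) == 0 || !nrow(cnvrs))
    return(flags)
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(df_granges(cnvrs),
                                df_granges(exclusion_track)))
  hit <- unique(S4Vectors::queryHits(h))
  flags[hit] <- list("telomere_centromere")
  flags
}

#' Flag the peninsula pattern
#'
#' A peninsula is a false-positive significant subregion at the variably
#' truncated edge of a common CNV: the calls contributing to the
#' significant span also extend into flanking probes that are not
#' significant. A region is flagged when at least `peninsula_fraction`
#' of its contributing calls cover `peninsula_extension_probes` or more
#' non-significant (`p >= alpha`) flanking probes beyond either boundary.
#'
#' @param cnvrs CNVR data frame.
#' @param calls CNV call table (post-QC).
#' @param probe_stats per-probe statistics used for segmentation.
#' @param marker_map marker map.
#' @param params a [filter_params()] object.
#' @param alpha the per-probe significance level used in segmentation.
#' @param samples optional sample frame to drop excluded samples' calls.
#' @return list of flag character vectors.
#' @export
flag_peninsula <- function(cnvrs, calls, probe_stats, marker_map,
                           params = filter_params(), alpha = 0.05,
                           samples = NULL) {
  if (!is.null(samples)) {
    inc <- included_samples(samples)
    calls <- calls[calls$sample_id %in% inc$sample_id, , drop = FALSE]
  }
  flags <- rep(list(character(0)), nrow(cnvrs))
  for (i in seq_len(nrow(cnvrs))) {
    type <- cnvrs$type[i]; ch <- cnvrs$chrom[i]
    ps <- probe_stats[probe_stats$type == type & probe_stats$chrom == ch, ,
                      drop = FALSE]
    if (!nrow(ps)) next
    pos <- ps$pos; pv <- ps$p
    is1 <- findInterval(cnvrs$start[i] - 1, pos) + 1L  # first probe in span
    ie <- findInterval(cnvrs$end[i], pos)              # last probe in span
    cc <- calls[calls$type == type & calls$chrom == ch &
                  calls$start <= cnvrs$end[i] &
                  calls$end >= cnvrs$start[i], , drop = FALSE]
    if (!nrow(cc)) next
    extends <- vapply(seq_len(nrow(cc)), function(j) {
      jl <- findInterval(cc$start[j] - 1, pos) + 1L
      jr <- findInterval(cc$end[j], pos)
      nl <- if (jl <= is1 - 1L) sum(pv[jl:(is1 - 1L)] >= alpha) else 0L
      nr <- if (jr >= ie + 1L) sum(pv[(ie + 1L):jr] >= alpha) else 0L
      max(nl, nr) >= params$peninsula_extension_probes
    }, TRUE)
    if (mean(extends) >= params$peninsula_fraction)
      flags[[i]] <- "peninsula"
  }
  flags
}

#' Flag GC-extreme and low-coverage CNVRs
#'
#' `gc_extreme` when the mean GC fraction of the span's probes falls
#' below `gc_low` or above `gc_high`; `gc_unknown` when no probe in the
#' span has a GC value; `low_coverage` when probe density over the span
#' falls below `min_probe_density` per 100 kb.
#'
#' @param cnvrs CNVR data frame.
#' @param marker_map marker map with `gc` column.
#' @param params a [filter_params()] object.
#' @return list of flag character vectors.
#' @export
flag_gc_and_coverage <- function(cnvrs, marker_map,
                                 params = filter_params()) {
  lapply(seq_len(nrow(cnvrs)), function(i) {
    idx <- probes_in_span(marker_map, cnvrs$chrom[i], cnvrs$start[i],
                          cnvrs$end[i])
    f <- character(0)
    gc <- marker_map$gc[idx]
    if (!length(gc) || all(is.na(gc))) {
      f <- c(f, "gc_unknown")
    } else {
      mg <- mean(gc, na.rm = TRUE)
      if (mg < params$gc_low || mg > params$gc_high) f <- c(f, "gc_extreme")
    }
    span_kb100 <- (cnvrs$end[i] - cnvrs$start[i] + 1) / 1e5
    if (length(idx) / span_kb100 < params$min_probe_density)
      f <- c(f, "low_coverage")
    f
  })
}

#' Flag CNVRs driven by recurrently contributing samples
#'
#' Samples carried in more than `max_cnvrs_per_sample` distinct
#' significant regions are bias samples (often atypical intensity
#' waves). A region is flagged `sample_bias` iff removing the bias
#' samples drops its enriched-cohort carrier count below
#' `min_case_carriers` or pushes its recomputed Fisher p above `alpha`;
#' a region whose signal survives the removal is kept unflagged.
#'
#' @param cnvrs CNVR data frame with `carriers_case`/`carriers_control`
#'   list columns (from [collapse_cnvrs()] with calls supplied).
#' @param n_cases,n_controls post-QC cohort sizes.
#' @param params a [filter_params()] object.
#' @param seg_params the [segmentation_params()] used upstream (supplies
#'   `min_case_carriers` and `alpha_probe`).
#' @return list of flag character vectors.
#' @export
flag_sample_bias <- function(cnvrs, n_cases, n_controls,
                             params = filter_params(),
                             seg_params = segmentation_params()) {
  flags <- rep(list(character(0)), nrow(cnvrs))
  if (!nrow(cnvrs)) return(flags)
  need_cols(cnvrs, c("carriers_case", "carriers_control"), "CNVR table")
  contrib <- mapply(c, cnvrs$carriers_case, cnvrs$carriers_control,
                    SIMPLIFY = FALSE)
  tallies <- table(unlist(lapply(contrib, unique)))
  bias_ids <- names(tallies)[tallies > params$max_cnvrs_per_sample]
  if (!length(bias_ids)) return(flags)
  for (i in seq_len(nrow(cnvrs))) {
    a2 <- length(setdiff(cnvrs$carriers_case[[i]], bias_ids))
    b2 <- length(setdiff(cnvrs$carriers_control[[i]], bias_ids))
    enriched <- if (cnvrs$direction[i] == "case_enriched") a2 else b2
    p2 <- fisher_exact_two_sided(a2, b2, n_cases, n_controls)
    if (enriched < seg_params$min_case_carriers ||
        p2 > seg_params$alpha_probe)
      flags[[i]] <- "sample_bias"
  }
  flags
}

#' Apply all CNVR filters
#'
#' Runs the positional, peninsula, GC/coverage and sample-bias screens
#' and writes the union of flags into `filter_flags` (comma-separated,
#' sorted; empty when clean). Recomputed from scratch each call, so the
#' operation is idempotent.
#'
#' @param cnvrs CNVR data frame from [collapse_cnvrs()] (with carrier
#'   list columns for the bias screen).
#' @param calls post-QC CNV call table.
#' @param samples QC-annotated sample data frame.
#' @param probe_stats per-probe statistics.
#' @param marker_map marker map.
#' @param exclusion_track optional telomere/centromere track.
#' @param params a [filter_params()] object.
#' @param seg_params the upstream [segmentation_params()].
#' @return `cnvrs` with `filter_flags` filled.
#' @export
apply_cnvr_filters <- function(cnvrs, calls, samples, probe_stats,
                               marker_map, exclusion_track = NULL,
                               params = filter_params(),
                               seg_params = segmentation_params()) {
  if (!nrow(cnvrs)) {
    cnvrs$filter_flags <- character(0)
    return(cnvrs)
  }
  sizes <- cohort_sizes(samples)
  cnvrs$filter_flags <- merge_flags(
    flag_positional_exclusions(cnvrs, exclusion_track),
    flag_peninsula(cnvrs, calls, probe_stats, marker_map, params,
                   alpha = seg_params$alpha_probe, samples = samples),
    flag_gc_and_coverage(cnvrs, marker_map, params),
    flag_sample_bias(cnvrs, sizes[["n_cases"]], sizes[["n_controls"]],
                     params, seg_params))
  cnvrs
}
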