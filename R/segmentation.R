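## Collapse of per-probe statistics into CNV regions (CNVRs). Runs of
## nominally significant probes sharing one CNV type and one enrichment
## direction, with consecutive significant probes at most one gap apart,
## form a region; the association is narrowed to the region's local
## p-value minimum (its best probe).

#' Segmentation parameters
#'
#' @param alpha_probe per-probe nominal significance level.
#' @param max_gap_bp maximum distance between consecutive significant
#'   probes within one region (1 Mb by default).
#' @param min_case_carriers minimum carrier count, in the enriched
#'   cohort at the best probe, for a region to be reported. Three
#'   carriers is the minimum recurrence giving any prospect of nominal
#'   significance and reproducibility for a rare CNV.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(alpha_probe = 0.05, max_gap_bp = 1e6,
                                min_case_carriers = 3L) {
  stopifnot(alpha_probe > 0, alpha_probe < 1, max_gap_bp > 0,
            min_case_carriers >= 0)
  structure(list(alpha_probe = alpha_probe, max_gap_bp = max_gap_bp,
                 min_case_carriers = as.integer(min_case_carriers)),
            class = "segmentation_params")
}

## internal: empty CNVR frame
empty_cnvrs <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   type = character(0), direction = character(0),
                   best_probe = character(0), best_pos = integer(0),
                   p_discovery = numeric(0), case_carriers = integer(0),
                   control_carriers = integer(0), n_probes_sig = integer(0),
                   filter_flags = character(0), genes = character(0),
                   stringsAsFactors = FALSE)
  df$carriers_case <- list()
  df$carriers_control <- list()
  df
}

#' Collapse significant probes into CNVRs
#'
#' Probes with `p < alpha_probe`, one CNV type and one enrichment
#' direction are chained while consecutive significant probes lie within
#' `max_gap_bp`; each chain becomes one region spanning its first to
#' last significant probe. The best probe is the chain's p-value
#' minimum (leftmost on ties); carrier counts are reported at the best
#' probe, and chains whose enriched-cohort carrier count there falls
#' below `min_case_carriers` are dropped. Deletions and duplications are
#' segmented independently, chains never cross chromosomes.
#'
#' @param probe_stats per-probe statistics (see
#'   [per_probe_association()]), sorted by position within chromosome.
#' @param params a [segmentation_params()] object.
#' @param calls optional call table; when given, per-region carrier
#'   sample ids at the best probe are attached (list columns
#'   `carriers_case` / `carriers_control`), which downstream filters
#'   need.
#' @param samples sample data frame, required with `calls`.
#' @return CNVR data frame, one row per region.
#' @export
collapse_cnvrs <- function(probe_stats, params = segmentation_params(),
                           calls = NULL, samples = NULL) {
  stopifnot(inherits(params, "segmentation_params"))
  need_cols(probe_stats, c("probe_id", "chrom", "pos", "type",
                           "case_carriers", "control_carriers", "p",
                           "enriched_in"), "probe statistics")
  ok <- vapply(split(probe_stats$pos,
                     list(probe_stats$chrom, probe_stats$type), drop = TRUE),
               function(p) !is.unsorted(p), TRUE)
  if (!all(ok)) stop("probe statistics are not sorted by position")
  if (!is.null(calls) && is.null(samples))
    stop("samples must be supplied with calls")

  out <- list()
  for (type in c("del", "dup")) {
    for (dir in c("case", "control")) {
      sig <- probe_stats[probe_stats$type == type &
                           probe_stats$p < params$alpha_probe &
                           probe_stats$enriched_in == dir, , drop = FALSE]
      if (!nrow(sig)) next
      for (ch in unique(sig$chrom)) {
        s <- sig[sig$chrom == ch, , drop = FALSE]
        chain <- cumsum(c(1L, diff(s$pos) > params$max_gap_bp))
        for (g in split(seq_len(nrow(s)), chain)) {
          blk <- s[g, , drop = FALSE]
          best <- which.min(blk$p)  # leftmost on ties
          a <- blk$case_carriers[best]; b <- blk$control_carriers[best]
          enriched <- if (dir == "case") a else b
          if (enriched < params$min_case_carriers) next
          row <- data.frame(
            chrom = ch, start = blk$pos[1], end = blk$pos[nrow(blk)],
            type = type, direction = paste0(dir, "_enriched"),
            best_probe = blk$probe_id[best], best_pos = blk$pos[best],
            p_discovery = blk$p[best], case_carriers = a,
            control_carriers = b, n_probes_sig = nrow(blk),
            filter_flags = "", genes = "", stringsAsFactors = FALSE)
          if (!is.null(calls)) {
            carr <- carriers_at_probe(calls, samples, ch, blk$pos[best], type)
            inc <- included_samples(samples)
            cases <- inc$sample_id[inc$cohort == "case"]
            row$carriers_case <- list(intersect(carr, cases))
            row$carriers_control <- list(setdiff(carr, cases))
          } else {
            row$carriers_case <- list(character(0))
            row$carriers_control <- list(character(0))
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (!length(out)) return(empty_cnvrs())
  cnvrs <- do.call(rbind, out)
  ord <- order(match(cnvrs$chrom, unique(probe_stats$chrom)), cnvrs$start,
               cnvrs$type)
  cnvrs <- cnvrs[ord, , drop = FALSE]
  rownames(cnvrs) <- NULL
  cnvrs
}

#' Collapse carrier-frequency-qualifying probes into testable regions
#'
#' The multiple-testing denominator of the scan is the number of regions
#' where a test could fire at all, not the number that happened to reach
#' significance: probes whose case carrier frequency meets
#' `min_case_frequency` (0.150% by default, i.e. at least
#' `ceiling(min_case_frequency * n_cases)` carriers — the minimal
#' recurrence from which frequency differences can reach nominal
#' significance, analogous to a minor-allele-frequency floor in SNP
#' association) are collapsed into maximal runs of consecutive
#' qualifying probes, per CNV type. Neighbouring probes covered by the
#' same calls carry redundant statistics, so a run is one test.
#'
#' @param probe_stats per-probe statistics or carrier counts (needs
#'   `chrom`, `pos`, `type`, `case_carriers` and the `n_cases`
#'   attribute or column).
#' @param min_case_frequency qualifying case carrier frequency.
#' @return data frame `chrom`, `start`, `end`, `type`, one row per
#'   testable region.
#' @export
testable_regions <- function(probe_stats, min_case_frequency = 0.0015) {
  n_cases <- attr(probe_stats, "n_cases")
  if (is.null(n_cases)) n_cases <- probe_stats$n_cases[1]
  if (is.null(n_cases)) stop("n_cases not available on probe_stats")
  min_carriers <- max(1L, ceiling(min_case_frequency * n_cases))
  out <- list()
  for (type in c("del", "dup")) {
    ps <- probe_stats[probe_stats$type == type, , drop = FALSE]
    for (ch in unique(ps$chrom)) {
      s <- ps[ps$chrom == ch, , drop = FALSE]
      q <- s$case_carriers >= min_carriers
      if (!any(q)) next
      r <- rle(q)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$pos[starts[keep]], end = s$pos[ends[keep]],
        type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Effective number of independent CNVR tests
#'
#' Counts distinct regions across the deletion and duplication
#' segmentations, merging regions whose spans overlap (a deletion and a
#' duplication region covering the same locus count once). Used to set
#' the Bonferroni bar.
#'
#' @param cnvrs_del,cnvrs_dup CNVR data frames from [collapse_cnvrs()];
#'   either may be empty. A single combined frame may be passed as
#'   `cnvrs_del` with `cnvrs_dup` empty or missing.
#' @return integer count of distinct regions.
#' @export
effective_test_count <- function(cnvrs_del, cnvrs_dup = NULL) {
  all <- rbind(cnvrs_del[c("chrom", "start", "end")],
               if (!is.null(cnvrs_dup)) cnvrs_dup[c("chrom", "start", "end")])
  n <- nrow(all)
  if (n == 0) return(0L)
  h <- GenomicRanges::findOverlaps(df_granges(all), df_granges(all))
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  keep <- q < s
  n_components(n, q[keep], s[keep])
}

#' Bonferroni multiple-testing bar
#'
#' @param n_tests effective number of tests (see
#'   [effective_test_count()]).
#' @param alpha family-wise error rate.
#' @return per-test significance threshold `alpha / n_tests`.
#' @export
bonferroni_bar <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  alpha / n_tests
}
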