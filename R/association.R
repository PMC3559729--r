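## Per-probe carrier counting and Fisher exact association. The scan
## statistic is a 2x2 table at every probe: carriers vs non-carriers of
## one CNV type (deletion = copy state 0/1, duplication = 3/4) in cases
## vs controls, with the full post-QC cohort sizes as denominators.

#' Two-sided Fisher exact p-value for a carrier 2x2 table
#'
#' Computes `P` for the table `[[a, N1-a], [b, N2-b]]` by the
#' minimum-likelihood two-sided rule: the sum of hypergeometric
#' probabilities, over all tables with the same margins, that do not
#' exceed the observed table's probability (relative tolerance 1e-7 in
#' the comparison, as in [stats::fisher.test()]). Vectorised over `a`
#' and `b`; repeated tables are evaluated once.
#'
#' @param a case carriers.
#' @param b control carriers.
#' @param n_cases case cohort size `N1`.
#' @param n_controls control cohort size `N2`.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_two_sided <- function(a, b, n_cases, n_controls) {
  if (length(n_cases) != 1 || length(n_controls) != 1)
    stop("cohort sizes must be scalars")
  k <- max(length(a), length(b))
  a <- rep_len(as.integer(a), k); b <- rep_len(as.integer(b), k)
  if (any(a < 0) || any(b < 0)) stop("negative carrier counts")
  if (any(a > n_cases) || any(b > n_controls))
    stop("carrier count exceeds cohort size")
  one <- function(a, b) {
    m <- a + b
    x <- max(0L, m - n_controls):min(m, n_cases)
    d <- stats::dhyper(x, n_cases, n_controls, m)
    po <- d[match(a, x)]
    min(1, sum(d[d <= po * (1 + 1e-7)]))
  }
  key <- paste(a, b)
  u <- !duplicated(key)
  pu <- mapply(one, a[u], b[u])
  unname(pu[match(key, key[u])])
}

#' Count deletion/duplication carriers at every probe
#'
#' A sample is a deletion carrier at a probe iff it has at least one
#' call with copy state 0/1 whose span covers the probe position
#' (duplications analogously, states 3/4); overlapping calls from the
#' same sample count once. Calls from QC-excluded samples are dropped.
#'
#' @param calls CNV call table.
#' @param marker_map marker map (the probe coordinate system).
#' @param samples sample data frame; rows with `included == FALSE` are
#'   ignored.
#' @return data frame with one row per probe per type: `probe_id`,
#'   `chrom`, `pos`, `type`, `case_carriers`, `control_carriers`, plus
#'   attributes `n_cases`/`n_controls` (included cohort sizes).
#' @export
count_carriers <- function(calls, marker_map, samples) {
  validate_calls(calls, marker_map)
  inc <- included_samples(samples)
  calls <- calls[calls$sample_id %in% inc$sample_id, , drop = FALSE]
  is_case <- inc$cohort == "case"
  samp_idx <- stats::setNames(seq_len(nrow(inc)), inc$sample_id)
  np <- nrow(marker_map)

  count_type <- function(type) {
    cc <- calls[calls$type == type, , drop = FALSE]
    ca <- integer(np); co <- integer(np)
    if (nrow(cc)) {
      probe <- integer(0); samp <- integer(0)
      for (ch in unique(cc$chrom)) {
        rows <- which(marker_map$chrom == ch)
        pos <- marker_map$pos[rows]
        sel <- cc$chrom == ch
        i1 <- findInterval(cc$start[sel] - 1, pos) + 1L
        i2 <- findInterval(cc$end[sel], pos)
        len <- pmax(i2 - i1 + 1L, 0L)
        keep <- len > 0L
        if (!any(keep)) next
        probe <- c(probe, rows[sequence(len[keep]) +
                                 rep(i1[keep] - 1L, len[keep])])
        samp <- c(samp, rep(samp_idx[cc$sample_id[sel][keep]], len[keep]))
      }
      if (length(probe)) {
        key <- (probe - 1) * nrow(inc) + samp  # < 2^53 for any real array
        keep <- !duplicated(key)
        probe <- probe[keep]; samp <- samp[keep]
        ca <- tabulate(probe[is_case[samp]], nbins = np)
        co <- tabulate(probe[!is_case[samp]], nbins = np)
      }
    }
    data.frame(probe_id = marker_map$probe_id, chrom = marker_map$chrom,
               pos = marker_map$pos, type = type, case_carriers = ca,
               control_carriers = co, stringsAsFactors = FALSE)
  }

  out <- rbind(count_type("del"), count_type("dup"))
  rownames(out) <- NULL
  attr(out, "n_cases") <- sum(is_case)
  attr(out, "n_controls") <- sum(!is_case)
  out
}

#' Per-probe Fisher exact association
#'
#' Adds the two-sided Fisher exact p-value and enrichment direction to a
#' carrier-count table. Probes with no carrier in either cohort get
#' `p = 1` and direction `"neither"`.
#'
#' @param counts output of [count_carriers()].
#' @param n_cases,n_controls cohort sizes; default taken from the
#'   attributes set by [count_carriers()].
#' @return probe-statistics data frame adding `n_cases`, `n_controls`,
#'   `p` and `enriched_in` columns.
#' @export
per_probe_association <- function(counts,
                                  n_cases = attr(counts, "n_cases"),
                                  n_controls = attr(counts, "n_controls")) {
  if (is.null(n_cases) || is.null(n_controls))
    stop("cohort sizes not given and not present as attributes")
  a <- counts$case_carriers; b <- counts$control_carriers
  p <- rep(1, length(a))
  nz <- a > 0 | b > 0
  p[nz] <- fisher_exact_two_sided(a[nz], b[nz], n_cases, n_controls)
  fa <- a / n_cases; fb <- b / n_controls
  stats_df <- counts
  stats_df$n_cases <- n_cases
  stats_df$n_controls <- n_controls
  stats_df$p <- p
  stats_df$enriched_in <- ifelse(fa > fb, "case",
                                 ifelse(fb > fa, "control", "neither"))
  attr(stats_df, "n_cases") <- n_cases
  attr(stats_df, "n_controls") <- n_controls
  stats_df
}

#' One-step per-probe association scan
#' @inheritParams count_carriers
#' @return probe-statistics data frame, see [per_probe_association()].
#' @export
probe_association <- function(calls, marker_map, samples) {
  per_probe_association(count_carriers(calls, marker_map, samples))
}

#' Carrier sample ids at a single probe
#'
#' @param calls CNV call table.
#' @param samples sample data frame (excluded samples ignored).
#' @param chrom,pos probe coordinate.
#' @param type `"del"` or `"dup"`.
#' @return character vector of sample ids.
#' @export
carriers_at_probe <- function(calls, samples, chrom, pos, type) {
  inc <- included_samples(samples)
  sel <- calls$type == type & calls$chrom == chrom &
    calls$start <= pos & calls$end >= pos &
    calls$sample_id %in% inc$sample_id
  unique(calls$sample_id[sel])
}

#' Carrier sample ids over a region (any overlap)
#'
#' @inheritParams carriers_at_probe
#' @param start,end region span, 1-based inclusive.
#' @param type `"del"`, `"dup"`, or `NULL` for either.
#' @return character vector of sample ids.
#' @export
carriers_in_region <- function(calls, samples, chrom, start, end,
                               type = NULL) {
  inc <- included_samples(samples)
  sel <- calls$chrom == chrom & calls$start <= end & calls$end >= start &
    calls$sample_id %in% inc$sample_id
  if (!is.null(type)) sel <- sel & calls$type == type
  unique(calls$sample_id[sel])
}
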