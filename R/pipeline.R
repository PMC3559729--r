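## End-to-end orchestration: sample QC -> per-probe carrier counting ->
## Fisher exact scan -> CNVR collapse -> artifact filters -> Bonferroni
## bar, and the replication stage with PC-corrected logistic tests and
## Fisher's-method combination. Both stages are deterministic given
## their inputs and keep a machine-readable log of counts per step.

#' Run the discovery stage
#'
#' @param marker_map marker map data frame.
#' @param samples sample sheet data frame.
#' @param calls CNV call table.
#' @param thresholds per-sample [qc_thresholds()].
#' @param seg_params [segmentation_params()].
#' @param filt_params [filter_params()].
#' @param exclusion_track optional telomere/centromere track.
#' @param gene_track optional gene-model track for annotation.
#' @param pairwise_identity optional duplicate-pair table for QC.
#' @param alpha family-wise error rate for the Bonferroni bar.
#' @return object of class `cnv_discovery`: list with `samples` (QC
#'   annotated), `probe_stats`, `cnvrs` (with `filter_flags`, `genes`
#'   and `pass_bar`), and `log`.
#' @export
run_discovery <- function(marker_map, samples, calls,
                          thresholds = qc_thresholds(),
                          seg_params = segmentation_params(),
                          filt_params = filter_params(),
                          exclusion_track = NULL, gene_track = NULL,
                          pairwise_identity = NULL, alpha = 0.05) {
  validate_marker_map(marker_map)
  samples <- apply_sample_qc(samples, calls, thresholds,
                             pairwise_identity = pairwise_identity)
  qc <- qc_summary(samples)
  calls_qc <- calls[calls$sample_id %in%
                      samples$sample_id[samples$included], , drop = FALSE]

  probe_stats <- probe_association(calls_qc, marker_map, samples)
  cnvrs <- collapse_cnvrs(probe_stats, seg_params, calls = calls_qc,
                          samples = samples)
  cnvrs <- apply_cnvr_filters(cnvrs, calls_qc, samples, probe_stats,
                              marker_map, exclusion_track = exclusion_track,
                              params = filt_params, seg_params = seg_params)
  if (!is.null(gene_track)) cnvrs <- annotate_genes(cnvrs, gene_track)

  testable <- testable_regions(probe_stats)
  n_tests <- effective_test_count(testable[testable$type == "del", ],
                                  testable[testable$type == "dup", ])
  bar <- if (n_tests > 0) bonferroni_bar(n_tests, alpha) else NA_real_
  cnvrs$pass_bar <- if (nrow(cnvrs))
    cnvrs$p_discovery < bar & !nzchar(cnvrs$filter_flags) else logical(0)

  log <- list(
    n_samples = nrow(samples),
    n_included = sum(samples$included),
    excluded_by_reason = qc[names(qc) != "included"],
    n_calls = nrow(calls), n_calls_post_qc = nrow(calls_qc),
    n_probes = nrow(marker_map),
    n_sig_probes = c(
      del = sum(probe_stats$type == "del" &
                  probe_stats$p < seg_params$alpha_probe),
      dup = sum(probe_stats$type == "dup" &
                  probe_stats$p < seg_params$alpha_probe)),
    n_cnvrs = c(del = sum(cnvrs$type == "del"),
                dup = sum(cnvrs$type == "dup")),
    n_cnvrs_flagged = sum(nzchar(cnvrs$filter_flags)),
    n_testable = c(del = sum(testable$type == "del"),
                   dup = sum(testable$type == "dup")),
    effective_tests = n_tests, bonferroni_bar = bar,
    n_pass_bar = sum(cnvrs$pass_bar))
  structure(list(samples = samples, probe_stats = probe_stats,
                 cnvrs = cnvrs, log = log),
            class = "cnv_discovery")
}

#' @export
print.cnv_discovery <- function(x, ...) {
  l <- x$log
  cat(sprintf(
    "CNV discovery: %d/%d samples included, %d calls, %d probes\n",
    l$n_included, l$n_samples, l$n_calls_post_qc, l$n_probes))
  cat(sprintf(
    "  significant probes: %d del / %d dup; CNVRs: %d del / %d dup (%d flagged)\n",
    l$n_sig_probes[["del"]], l$n_sig_probes[["dup"]],
    l$n_cnvrs[["del"]], l$n_cnvrs[["dup"]], l$n_cnvrs_flagged))
  cat(sprintf(
    "  effective tests: %d, Bonferroni bar: %.3g, passing: %d\n",
    l$effective_tests, l$bonferroni_bar, l$n_pass_bar))
  invisible(x)
}

#' Run the replication stage
#'
#' For each discovery CNVR, carrier status in the replication cohort is
#' evaluated over the discovery span with any-overlap semantics, tested
#' with PC-corrected logistic regression, and gated on replicating in
#' the same direction before Fisher's-method combination with the
#' discovery p-value. The genomic inflation factor over the replication
#' p-values is reported in the log.
#'
#' @param discovery a `cnv_discovery` object or a CNVR data frame.
#' @param rep_calls replication-cohort CNV call table.
#' @param rep_samples replication sample sheet; must carry at least
#'   `n_pcs` principal-component columns.
#' @param n_pcs number of leading PCs used as covariates.
#' @param alpha replication significance level.
#' @return list with `cnvrs` (adding replication carrier counts,
#'   `p_replication`, `replicated_same_direction`, `replicated`,
#'   `p_combined`, `separation_detected`) and `log` (with `lambda`).
#' @export
run_replication <- function(discovery, rep_calls, rep_samples, n_pcs = 3L,
                            alpha = 0.05) {
  cnvrs <- if (inherits(discovery, "cnv_discovery")) discovery$cnvrs
           else discovery
  pc_cols <- paste0("PC", seq_len(n_pcs))
  if (!all(pc_cols %in% names(rep_samples)))
    stop("replication sample sheet lacks PC column(s): ",
         paste(setdiff(pc_cols, names(rep_samples)), collapse = ", "))
  inc <- included_samples(rep_samples)
  rep_calls <- rep_calls[rep_calls$sample_id %in% inc$sample_id, ,
                         drop = FALSE]
  n1 <- sum(inc$cohort == "case"); n2 <- sum(inc$cohort == "control")

  k <- nrow(cnvrs)
  cnvrs$case_carriers_rep <- integer(k)
  cnvrs$control_carriers_rep <- integer(k)
  cnvrs$p_replication <- rep(NA_real_, k)
  cnvrs$separation_detected <- rep(NA, k)
  cnvrs$replicated_same_direction <- rep(FALSE, k)
  cnvrs$replicated <- rep(FALSE, k)
  cnvrs$p_combined <- rep(NA_real_, k)

  for (i in seq_len(k)) {
    carr_ids <- carriers_in_region(rep_calls, inc, cnvrs$chrom[i],
                                   cnvrs$start[i], cnvrs$end[i],
                                   type = cnvrs$type[i])
    carrier <- as.integer(inc$sample_id %in% carr_ids)
    a <- sum(carrier[inc$cohort == "case"])
    b <- sum(carrier[inc$cohort == "control"])
    cnvrs$case_carriers_rep[i] <- a
    cnvrs$control_carriers_rep[i] <- b
    if (a + b == 0) next  # locus absent from the replication set
    fit <- logistic_cnv_association(carrier, inc$cohort,
                                    pcs = inc[pc_cols])
    cnvrs$p_replication[i] <- fit$p
    cnvrs$separation_detected[i] <- fit$separation_detected
    rep_dir <- if (a / n1 > b / n2) "case_enriched"
               else if (b / n2 > a / n1) "control_enriched" else "neither"
    same <- rep_dir == cnvrs$direction[i]
    cnvrs$replicated_same_direction[i] <- same
    cnvrs$replicated[i] <- same && !is.na(fit$p) && fit$p < alpha
    if (same)
      cnvrs$p_combined[i] <-
        fisher_combine(c(cnvrs$p_discovery[i],
                         max(fit$p, .Machine$double.xmin)))$p_combined
  }
  lambda <- if (any(!is.na(cnvrs$p_replication)))
    genomic_inflation(cnvrs$p_replication[!is.na(cnvrs$p_replication)])
  else NA_real_
  list(cnvrs = cnvrs,
       log = list(n_rep_cases = n1, n_rep_controls = n2,
                  n_tested = sum(!is.na(cnvrs$p_replication)),
                  n_replicated = sum(cnvrs$replicated), lambda = lambda))
}
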