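#' Per-sample quality-control thresholds
#'
#' All comparisons are strict, so a sample sitting exactly on a
#' threshold fails it: inclusion requires call rate *above* 98%, LRR
#' standard deviation *below* 0.30, |GC wave factor| *below* 0.05 and
#' CNV call count *below* 100. `pca_sd_limit` operationalises the
#' ancestry screen as a distance limit (in standard deviations) from the
#' included-set centroid on each of the first two principal components.
#'
#' @param min_call_rate minimum genotyping call rate (exclusive).
#' @param max_lrr_sd maximum per-sample LRR standard deviation (exclusive).
#' @param max_abs_gcwf maximum |GC wave factor| (exclusive).
#' @param max_cnv_count maximum PennCNV call count (exclusive).
#' @param pca_sd_limit PC1/PC2 centroid distance limit in SD units.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, max_lrr_sd = 0.30,
                          max_abs_gcwf = 0.05, max_cnv_count = 100L,
                          pca_sd_limit = 6.0) {
  stopifnot(min_call_rate > 0, max_lrr_sd > 0, max_abs_gcwf > 0,
            max_cnv_count > 0, pca_sd_limit > 0)
  structure(list(min_call_rate = min_call_rate, max_lrr_sd = max_lrr_sd,
                 max_abs_gcwf = max_abs_gcwf,
                 max_cnv_count = as.integer(max_cnv_count),
                 pca_sd_limit = pca_sd_limit),
            class = "qc_thresholds")
}

## internal: duplicate exclusions via connected components; from each
## cluster the lexicographically smallest id is kept
duplicate_exclusions <- function(ids, pairwise_identity, threshold) {
  if (is.null(pairwise_identity) || nrow(pairwise_identity) == 0)
    return(character(0))
  pi <- pairwise_identity
  names(pi)[1:3] <- c("id1", "id2", "identity")
  if (any(pi$identity < 0 | pi$identity > 1))
    stop("pairwise identity fractions must lie in [0, 1]")
  unknown <- setdiff(c(pi$id1, pi$id2), ids)
  if (length(unknown))
    stop("unknown sample id(s) in duplicate pairs: ",
         paste(unknown, collapse = ", "))
  pi <- pi[pi$identity > threshold, , drop = FALSE]
  if (!nrow(pi)) return(character(0))
  nodes <- sort(unique(c(pi$id1, pi$id2)))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  for (k in seq_len(nrow(pi))) {
    a <- find(match(pi$id1[k], nodes)); b <- find(match(pi$id2[k], nodes))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(nodes), find, 1L)
  drop <- unlist(lapply(split(nodes, comp), function(cl) sort(cl)[-1]),
                 use.names = FALSE)
  drop
}

#' Flag duplicate samples from pairwise identity
#'
#' From every cluster of samples connected by identity above the
#' threshold (e.g. monozygotic twins or repeated DNA), exactly one
#' sample — the lexicographically smallest id — is retained; the rest
#' are excluded with reason `"duplicate"`.
#'
#' @param samples sample data frame.
#' @param pairwise_identity data frame `(id1, id2, identity)` with
#'   identity fractions in `[0,1]`.
#' @param threshold identity above which a pair is a duplicate.
#' @return samples with `included`/`exclusion_reason` updated.
#' @export
flag_duplicates <- function(samples, pairwise_identity, threshold = 0.99) {
  drop <- duplicate_exclusions(samples$sample_id, pairwise_identity, threshold)
  if (!"included" %in% names(samples)) samples$included <- TRUE
  if (!"exclusion_reason" %in% names(samples)) samples$exclusion_reason <- ""
  hit <- samples$sample_id %in% drop & samples$included
  samples$included[hit] <- FALSE
  samples$exclusion_reason[hit] <- "duplicate"
  samples
}

#' Apply per-sample quality control
#'
#' A sample is included iff `call_rate > min_call_rate`,
#' `lrr_sd < max_lrr_sd`, `|gcwf| < max_abs_gcwf`,
#' `cnv_count < max_cnv_count`, it is not a flagged duplicate, and it
#' lies within `pca_sd_limit` standard deviations of the included-set
#' centroid on PC1 and PC2 (centroid recomputed over two rounds).
#' Every exclusion records the first failing reason, in that order.
#'
#' @param samples sample data frame.
#' @param calls optional CNV call table; used to fill `cnv_count` where
#'   it is missing (`NA`).
#' @param thresholds a [qc_thresholds()] object.
#' @param pairwise_identity optional duplicate-pair table, see
#'   [flag_duplicates()].
#' @param duplicate_threshold identity threshold for duplicate pairs.
#' @return samples with `included` and `exclusion_reason` set.
#' @export
apply_sample_qc <- function(samples, calls = NULL,
                            thresholds = qc_thresholds(),
                            pairwise_identity = NULL,
                            duplicate_threshold = 0.99) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need_cols(samples, c("sample_id", "cohort", "call_rate", "lrr_sd",
                       "gcwf", "cnv_count"), "sample sheet")
  if (anyDuplicated(samples$sample_id)) stop("sample ids are not unique")
  if (any(is.na(samples$cnv_count))) {
    if (is.null(calls))
      stop("cnv_count missing for sample ",
           samples$sample_id[which(is.na(samples$cnv_count))[1]],
           " and no calls supplied to derive it")
    counted <- table(calls$sample_id)
    na <- is.na(samples$cnv_count)
    samples$cnv_count[na] <-
      as.integer(counted[samples$sample_id[na]])
    samples$cnv_count[is.na(samples$cnv_count)] <- 0L
  }
  for (field in c("call_rate", "lrr_sd", "gcwf", "cnv_count")) {
    if (any(is.na(samples[[field]])))
      stop("missing QC metric '", field, "' for sample ",
           samples$sample_id[which(is.na(samples[[field]]))[1]])
  }

  reason <- rep("", nrow(samples))
  fail <- function(cond, tag) reason <<- ifelse(reason == "" & cond, tag, reason)
  fail(!(samples$call_rate > thresholds$min_call_rate), "call_rate")
  fail(!(samples$lrr_sd < thresholds$max_lrr_sd), "lrr_sd")
  fail(!(abs(samples$gcwf) < thresholds$max_abs_gcwf), "gcwf")
  fail(!(samples$cnv_count < thresholds$max_cnv_count), "cnv_count")
  dup <- duplicate_exclusions(samples$sample_id, pairwise_identity,
                              duplicate_threshold)
  fail(samples$sample_id %in% dup, "duplicate")

  ## ancestry screen: two rounds of PC1/PC2 centroid distance
  if (all(c("PC1", "PC2") %in% names(samples))) {
    for (round in 1:2) {
      inc <- reason == ""
      for (pc in c("PC1", "PC2")) {
        mu <- mean(samples[[pc]][inc]); s <- stats::sd(samples[[pc]][inc])
        if (is.na(s) || s == 0) next
        out <- abs(samples[[pc]] - mu) > thresholds$pca_sd_limit * s
        reason <- ifelse(reason == "" & out, "pca_outlier", reason)
      }
    }
  }

  samples$included <- reason == ""
  samples$exclusion_reason <- reason
  samples
}

#' Summarise QC exclusions
#' @param samples QC-annotated sample data frame.
#' @return named integer vector of exclusion counts per reason.
#' @export
qc_summary <- function(samples) {
  r <- samples$exclusion_reason[!samples$included]
  c(table(factor(r, levels = c("call_rate", "lrr_sd", "gcwf", "cnv_count",
                               "duplicate", "pca_outlier"))),
    included = sum(samples$included))
}
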