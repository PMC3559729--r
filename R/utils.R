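#' Map a PennCNV copy state to a CNV type
#'
#' Copy states 0 and 1 are deletions, 3 and 4 duplications. State 2
#' (diploid) is not a CNV and is rejected.
#'
#' @param copy_state integer vector of copy numbers in `{0, 1, 3, 4}`.
#' @return character vector, `"del"` or `"dup"`.
#' @export
cnv_type <- function(copy_state) {
  if (any(!copy_state %in% c(0L, 1L, 3L, 4L)))
    stop("copy_state must be in {0, 1, 3, 4}; state 2 is diploid, not a CNV")
  ifelse(copy_state < 2L, "del", "dup")
}

## internal: stop unless all columns are present
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Validate a marker map
#'
#' A marker map is the probe coordinate system for all statistics: a
#' data frame with columns `probe_id`, `chrom`, `pos` (1-based bp) and
#' `gc` (fraction in `[0,1]`, `NA` allowed). Positions must be strictly
#' increasing within each chromosome and probe ids unique.
#'
#' @param map data frame.
#' @return the map, invisibly, after validation.
#' @export
validate_marker_map <- function(map) {
  need_cols(map, c("probe_id", "chrom", "pos", "gc"), "marker map")
  if (anyDuplicated(map$probe_id))
    stop("marker map probe_ids are not unique")
  ok <- vapply(split(map$pos, map$chrom), function(p) all(diff(p) > 0), TRUE)
  if (!all(ok))
    stop("marker map positions not strictly increasing on: ",
         paste(names(ok)[!ok], collapse = ", "))
  gc <- map$gc[!is.na(map$gc)]
  if (length(gc) && (any(gc < 0) || any(gc > 1)))
    stop("marker map gc values must lie in [0, 1]")
  invisible(map)
}

## internal: validate a CNV call table against an optional marker map
validate_calls <- function(calls, marker_map = NULL) {
  need_cols(calls, c("sample_id", "chrom", "start", "end", "copy_state",
                     "n_probes"), "CNV call table")
  if (any(calls$start > calls$end))
    stop("CNV call with start > end")
  cnv_type(calls$copy_state)  # rejects state 2
  if (!is.null(marker_map)) {
    bad <- setdiff(unique(calls$chrom), unique(marker_map$chrom))
    if (length(bad))
      stop("CNV calls on chromosome(s) absent from the marker map: ",
           paste(bad, collapse = ", "))
  }
  invisible(calls)
}

## internal: probe row indices of `map` covered by [start, end] on chrom.
## Relies on per-chromosome sorted positions (validated at read time).
probes_in_span <- function(marker_map, chrom, start, end) {
  idx <- which(marker_map$chrom == chrom)
  if (!length(idx)) return(integer(0))
  pos <- marker_map$pos[idx]
  i1 <- findInterval(start - 1, pos) + 1L
  i2 <- findInterval(end, pos)
  if (i2 < i1) return(integer(0))
  idx[i1:i2]
}

## internal: format a region label
region_label <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

## internal: GRanges from chrom/start/end columns
df_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

## internal: union-find connected components; edges as (from, to) indices
n_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

## internal: included-sample accessor (missing column means all included)
included_samples <- function(samples) {
  if ("included" %in% names(samples)) samples[samples$included, , drop = FALSE]
  else samples
}

## internal: cohort sizes of the included set
cohort_sizes <- function(samples) {
  s <- included_samples(samples)
  c(n_cases = sum(s$cohort == "case"), n_controls = sum(s$cohort == "control"))
}
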