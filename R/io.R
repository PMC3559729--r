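## File formats. Internal coordinates are 1-based inclusive (the PennCNV
## call convention); BED input is converted at the boundary.

#' Read a PennCNV-style CNV call file
#'
#' One call per line, e.g.
#' `chr1:6240656-6289806 numsnp=12 length=49,151 state2,cn=1 SAMP1`.
#' The `cn=` field is the copy number; diploid calls (`cn=2`) are
#' rejected. The sample identifier is the token following the state
#' field; trailing `startsnp=`/`endsnp=` tokens are ignored.
#'
#' @param path path to the call file.
#' @param marker_map optional marker map; when given, chromosomes are
#'   checked against it and each call's `numsnp` is cross-checked against
#'   the number of map probes inside the call span.
#' @return data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `n_probes`, `type`.
#' @export
read_cnv_calls <- function(path, marker_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      copy_state = integer(0), n_probes = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  parse_line <- function(tk, i) {
    m <- regmatches(tk[1], regexec("^(\\S+):(\\d+)-(\\d+)$", tk[1]))[[1]]
    ns <- grep("^numsnp=\\d+$", tk, value = TRUE)
    cn <- grep("^(state\\d+,)?cn=\\d+$", tk)
    if (length(m) != 4 || length(ns) != 1 || length(cn) != 1 ||
        cn[1] >= length(tk))
      stop("malformed CNV call at line ", i, ": ", paste(tk, collapse = " "))
    state <- as.integer(sub("^.*cn=", "", tk[cn]))
    if (state == 2L)
      stop("diploid call (cn=2) at line ", i, "; state 2 is not a CNV")
    list(sample_id = tk[cn + 1L], chrom = m[2], start = as.integer(m[3]),
         end = as.integer(m[4]), copy_state = state,
         n_probes = as.integer(sub("numsnp=", "", ns)))
  }
  parsed <- mapply(parse_line, toks, seq_along(toks), SIMPLIFY = FALSE)
  calls <- data.frame(
    sample_id = vapply(parsed, `[[`, "", "sample_id"),
    chrom = vapply(parsed, `[[`, "", "chrom"),
    start = vapply(parsed, `[[`, 1L, "start"),
    end = vapply(parsed, `[[`, 1L, "end"),
    copy_state = vapply(parsed, `[[`, 1L, "copy_state"),
    n_probes = vapply(parsed, `[[`, 1L, "n_probes"),
    stringsAsFactors = FALSE)
  calls$type <- cnv_type(calls$copy_state)
  validate_calls(calls, marker_map)
  if (!is.null(marker_map)) {
    k <- vapply(seq_len(nrow(calls)), function(i)
      length(probes_in_span(marker_map, calls$chrom[i], calls$start[i],
                            calls$end[i])), 1L)
    bad <- which(k != calls$n_probes)
    if (length(bad))
      stop("numsnp mismatch with marker map at line ", bad[1], ": stated ",
           calls$n_probes[bad[1]], ", map has ", k[bad[1]])
  }
  calls
}

#' Write CNV calls in PennCNV-style text format
#'
#' @param calls CNV call data frame (see [read_cnv_calls()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  validate_calls(calls)
  state_code <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  lines <- sprintf("%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s",
                   calls$chrom, calls$start, calls$end, calls$n_probes,
                   formatC(calls$end - calls$start + 1L, big.mark = ",",
                           format = "d"),
                   state_code[as.character(calls$copy_state)],
                   calls$copy_state, calls$sample_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker map
#'
#' Tab-separated with header `probe_id chrom pos gc`; `gc` may be `NA`.
#'
#' @param path file path.
#' @return validated marker map data frame.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(map, c("probe_id", "chrom", "pos", "gc"), "marker map file")
  map$pos <- as.integer(map$pos)
  map$gc <- as.numeric(map$gc)
  validate_marker_map(map)
  map
}

#' Write a marker map
#' @param map marker map data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  utils::write.table(map[c("probe_id", "chrom", "pos", "gc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header; required columns `sample_id`, `cohort`
#' (`case`/`control`), `call_rate`, `lrr_sd`, `gcwf`, `cnv_count`, plus
#' principal-component columns `PC1`, `PC2`, ... Optional `included` and
#' `exclusion_reason` columns are initialised when absent.
#'
#' @param path file path.
#' @return sample data frame.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(s, c("sample_id", "cohort", "call_rate", "lrr_sd", "gcwf",
                 "cnv_count"), "sample sheet")
  if (anyDuplicated(s$sample_id)) stop("sample ids are not unique")
  if (!all(s$cohort %in% c("case", "control")))
    stop("cohort must be 'case' or 'control'")
  if (!"included" %in% names(s)) s$included <- TRUE
  if (!"exclusion_reason" %in% names(s)) s$exclusion_reason <- ""
  s$exclusion_reason[is.na(s$exclusion_reason)] <- ""
  s
}

#' Write a sample sheet
#' @param samples sample data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval track
#'
#' Three or more columns: chrom, start, end, optional name. BED starts
#' are 0-based half-open and are converted to the package's 1-based
#' inclusive convention. Intervals are sorted by (chrom, start);
#' overlapping intervals are preserved, never merged.
#'
#' @param path file path.
#' @param role `"exclusion_region"` (telomere/centromere cytobands) or
#'   `"gene_model"` (UCSC-style transcript spans, introns included).
#' @return data frame `chrom`, `start`, `end`, `name` with a `"role"`
#'   attribute.
#' @export
read_interval_track <- function(path, role = c("exclusion_region", "gene_model")) {
  role <- match.arg(role)
  bed <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("interval track needs >= 3 columns")
  if (any(bed[[2]] >= bed[[3]]))
    stop("interval with start >= end (BED half-open convention)")
  track <- data.frame(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    name = if (ncol(bed) >= 4) as.character(bed[[4]])
           else sprintf("%s_%d", role, seq_len(nrow(bed))),
    stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  attr(track, "role") <- role
  track
}

## association-table columns; "." stands for an empty flag/gene field
assoc_cols <- c("region", "type", "case_carriers", "control_carriers",
                "p_discovery", "p_replication", "p_combined",
                "filter_flags", "genes")

fmt_p <- function(p) ifelse(is.na(p), "NA", format(p, digits = 15))

#' Write a CNVR association table
#'
#' Tab-separated, one row per CNVR with columns `region`, `type`,
#' `case_carriers`, `control_carriers`, `p_discovery`, `p_replication`,
#' `p_combined`, `filter_flags`, `genes`. Round-trips through
#' [read_association_table()].
#'
#' @param cnvrs CNVR data frame (see [collapse_cnvrs()]); may be empty.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_association_table <- function(cnvrs, path) {
  n <- nrow(cnvrs)
  get <- function(col, default) {
    if (col %in% names(cnvrs)) cnvrs[[col]] else rep(default, n)
  }
  out <- data.frame(
    region = if (n) region_label(cnvrs$chrom, cnvrs$start, cnvrs$end)
             else character(0),
    type = get("type", character(0)),
    case_carriers = get("case_carriers", NA_integer_),
    control_carriers = get("control_carriers", NA_integer_),
    p_discovery = fmt_p(get("p_discovery", NA_real_)),
    p_replication = fmt_p(get("p_replication", NA_real_)),
    p_combined = fmt_p(get("p_combined", NA_real_)),
    filter_flags = {
      f <- get("filter_flags", character(0)); ifelse(nzchar(f), f, ".")
    },
    genes = {
      g <- get("genes", character(0)); ifelse(nzchar(g), g, ".")
    },
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(assoc_cols, collapse = "\t"), con)
  if (n)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CNVR association table written by [write_association_table()]
#'
#' @param path file path.
#' @return CNVR data frame with `chrom`, `start`, `end` recovered from
#'   the region label.
#' @export
read_association_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need_cols(t, assoc_cols, "association table")
  m <- regmatches(t$region, regexec("^(.+):(\\d+)-(\\d+)$", t$region))
  if (any(lengths(m) != 4)) stop("malformed region label in association table")
  data.frame(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4)),
    type = t$type,
    case_carriers = as.integer(t$case_carriers),
    control_carriers = as.integer(t$control_carriers),
    p_discovery = as.numeric(t$p_discovery),
    p_replication = suppressWarnings(as.numeric(t$p_replication)),
    p_combined = suppressWarnings(as.numeric(t$p_combined)),
    filter_flags = ifelse(t$filter_flags == ".", "", t$filter_flags),
    genes = ifelse(t$genes == ".", "", t$genes),
    stringsAsFactors = FALSE)
}
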