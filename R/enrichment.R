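## Gene annotation of CNVRs and functional-category enrichment. Any
## 1-bp overlap with a gene span (introns included) is a hit; regions in
## gene deserts are annotated with the nearest proximal gene. Category
## enrichment is a one-sided hypergeometric over-representation test
## against the array background, with each CNV locus limited to
## contributing one gene per category so that clustered gene families
## cannot inflate a category on their own.

#' Annotate CNVRs with overlapped or nearest genes
#'
#' All genes overlapping the region span by at least 1 bp are attached
#' in genomic order; when none overlaps, the single nearest gene by edge
#' distance is attached (ties broken towards the smaller start) and the
#' mode is `"proximal"`.
#'
#' @param cnvrs CNVR data frame.
#' @param genes gene-model interval track (role `gene_model`, transcript
#'   spans including introns).
#' @return `cnvrs` with `genes` (comma-separated) and `gene_mode`
#'   (`"overlap"`, `"proximal"`, or `"none"` when the chromosome has no
#'   genes) columns filled.
#' @export
annotate_genes <- function(cnvrs, genes) {
  cnvrs$genes <- rep("", nrow(cnvrs))
  cnvrs$gene_mode <- rep("none", nrow(cnvrs))
  if (!nrow(cnvrs) || is.null(genes) || !nrow(genes)) return(cnvrs)
  gr_c <- df_granges(cnvrs)
  gr_g <- df_granges(genes)
  # tracks may legitimately cover different chromosome sets
  h <- suppressWarnings(GenomicRanges::findOverlaps(gr_c, gr_g))
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  for (i in seq_len(nrow(cnvrs))) {
    hit <- s[q == i]
    if (length(hit)) {
      hit <- hit[order(genes$start[hit], genes$end[hit])]
      cnvrs$genes[i] <- paste(unique(genes$name[hit]), collapse = ",")
      cnvrs$gene_mode[i] <- "overlap"
    }
  }
  for (i in which(cnvrs$gene_mode == "none")) {
    same <- which(genes$chrom == cnvrs$chrom[i])
    if (!length(same)) next  # no gene on this chromosome
    d <- GenomicRanges::distance(gr_c[i], gr_g[same])
    best <- same[d == min(d)]
    best <- best[order(genes$start[best])][1]  # ties: smaller start
    cnvrs$genes[i] <- genes$name[best]
    cnvrs$gene_mode[i] <- "proximal"
  }
  cnvrs
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), order preserved, capped at 1.
#'
#' @param p_list vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p_list) {
  if (any(p_list < 0 | p_list > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_list, method = "BH")
}

#' Functional-category enrichment with the one-gene-per-locus rule
#'
#' For each category, the hit count is the number of loci contributing
#' at least one member gene — a locus spanning several genes of the same
#' category contributes exactly one hit, so clustered gene families
#' cannot drive enrichment. The raw p-value is the one-sided
#' hypergeometric over-representation tail (drawing one gene per locus
#' from the array background); adjustment across categories is
#' Benjamini-Hochberg.
#'
#' @param locus_gene_lists list with one character vector of genes per
#'   CNV locus.
#' @param categories data frame with columns `gene` and `category`
#'   (a gene may belong to several categories).
#' @param background character vector of all genes covered by the array;
#'   must contain every locus gene.
#' @return data frame `category`, `hits_in_list`, `list_size`,
#'   `hits_in_background`, `background_size`, `p_raw`, `p_bh`, ordered
#'   by `p_raw`.
#' @export
enrichment_test <- function(locus_gene_lists, categories, background) {
  need_cols(categories, c("gene", "category"), "category table")
  background <- unique(background)
  listed <- unique(unlist(locus_gene_lists))
  missing <- setdiff(listed, background)
  if (length(missing))
    stop("gene(s) absent from background: ", paste(missing, collapse = ", "))
  categories <- categories[categories$gene %in% background, , drop = FALSE]
  n_loci <- length(locus_gene_lists)
  N <- length(background)
  cats <- unique(categories$category)
  members <- split(categories$gene, categories$category)
  res <- do.call(rbind, lapply(cats, function(cat) {
    M <- unique(members[[cat]])
    hits <- sum(vapply(locus_gene_lists,
                       function(g) any(g %in% M), TRUE))
    K <- length(M)
    p <- stats::phyper(hits - 1, K, N - K, n_loci, lower.tail = FALSE)
    data.frame(category = cat, hits_in_list = hits, list_size = n_loci,
               hits_in_background = K, background_size = N, p_raw = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(category = character(0), hits_in_list = integer(0),
                      list_size = integer(0), hits_in_background = integer(0),
                      background_size = integer(0), p_raw = numeric(0),
                      p_bh = numeric(0), stringsAsFactors = FALSE))
  res$p_bh <- benjamini_hochberg(res$p_raw)
  res <- res[order(res$p_raw, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}
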