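# shared filter fixture: a discovery run on a small cohort with one
# clean planted region, one inside an excluded band, one on GC-extreme
# probes, a peninsula and recurrent bias samples
filter_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(
      n_cases = 800, n_controls = 400, chrom_count = 2,
      n_probes_per_chrom = 600,
      planted_cnvrs = list(
        planted_cnvr("chr1", 200, 215, "del", 25, 0),
        planted_cnvr("chr1", 10, 20, "del", 25, 0),     # telomere band
        planted_cnvr("chr2", 520, 540, "dup", 25, 0)),  # GC-extreme zone
      peninsulas = list(
        planted_peninsula("chr2", 100, 140, edge_probes = 8,
                          common_rate = 0.05, edge_case_carriers = 20,
                          type = "dup")),
      # bias loci are pairwise more than 1 Mb apart so they cannot chain
      # into one region, and dup so they cannot chain with the clean del
      bias_samples = 12, bias_loci = lapply(c(60, 180, 370, 490),
        function(s) list(chrom = "chr1", start_probe = s,
                         end_probe = s + 7L, type = "dup")),
      boundary_jitter_probes = 2, seed = 77)
    sim <- simulate_dataset(cfg)
    tracks <- demo_tracks(cfg)
    d <- run_discovery(sim$marker_map, sim$samples, sim$calls,
                       exclusion_track = tracks$exclusion)
    cache <<- list(cfg = cfg, sim = sim, tracks = tracks, d = d)
    cache
  }
})

overlapping_row <- function(cnvrs, chrom, start, end, type) {
  which(cnvrs$chrom == chrom & cnvrs$start <= end & cnvrs$end >= start &
          cnvrs$type == type)
}

test_that("positional exclusion flags any 1-bp cytoband overlap, strictly", {
  cnvrs <- data.frame(chrom = "chr1", start = c(50L, 101L, 150L),
                      end = c(100L, 120L, 200L), type = "del",
                      stringsAsFactors = FALSE)
  track <- data.frame(chrom = "chr1", start = 1L, end = 100L,
                      name = "ptel", stringsAsFactors = FALSE)
  fl <- flag_positional_exclusions(cnvrs, track)
  expect_equal(fl, list("telomere_centromere", character(0), character(0)))
  expect_equal(flag_positional_exclusions(cnvrs, track[0, ]),
               rep(list(character(0)), 3))
})

test_that("GC and coverage screens use span means and probe density", {
  map <- toy_map(20, gc = 0.8)
  cnvr_hi <- data.frame(chrom = "chr1", start = 10000L, end = 50000L,
                        type = "del")
  expect_equal(flag_gc_and_coverage(cnvr_hi, map)[[1]], "gc_extreme")

  map_mid <- toy_map(20, gc = 0.5)
  expect_equal(flag_gc_and_coverage(cnvr_hi, map_mid)[[1]], character(0))

  # 2 probes over 500 kb is 0.4 probes / 100 kb < 1.0
  sparse <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                       pos = c(10000L, 500000L), gc = 0.5)
  wide <- data.frame(chrom = "chr1", start = 10000L, end = 509999L,
                     type = "del")
  expect_equal(flag_gc_and_coverage(wide, sparse)[[1]], "low_coverage")

  map_na <- toy_map(20, gc = NA_real_)
  expect_equal(flag_gc_and_coverage(cnvr_hi, map_na)[[1]], "gc_unknown")
})

test_that("the peninsula filter separates truncation artifacts from clean regions", {
  fx <- filter_fixture()
  cv <- fx$d$cnvrs
  pen <- fx$sim$truth$peninsulas
  i <- overlapping_row(cv, pen$chrom, pen$edge_start, pen$edge_end, pen$type)
  expect_true(length(i) >= 1)
  expect_true(any(grepl("peninsula", cv$filter_flags[i])))

  clean <- fx$sim$truth$planted[1, ]
  j <- overlapping_row(cv, clean$chrom, clean$start, clean$end, clean$type)
  expect_true(length(j) == 1)
  expect_false(grepl("peninsula", cv$filter_flags[j]))

  # brute-force check of the extension-fraction rule at the flagged region
  i <- i[grepl("peninsula", cv$filter_flags[i])][1]
  calls <- fx$sim$calls
  calls <- calls[calls$sample_id %in%
                   fx$d$samples$sample_id[fx$d$samples$included], ]
  ps <- fx$d$probe_stats
  ps <- ps[ps$type == cv$type[i] & ps$chrom == cv$chrom[i], ]
  cc <- calls[calls$type == cv$type[i] & calls$chrom == cv$chrom[i] &
                calls$start <= cv$end[i] & calls$end >= cv$start[i], ]
  ext <- vapply(seq_len(nrow(cc)), function(k) {
    left <- ps$pos >= cc$start[k] & ps$pos < cv$start[i] & ps$p >= 0.05
    right <- ps$pos > cv$end[i] & ps$pos <= cc$end[k] & ps$p >= 0.05
    max(sum(left), sum(right)) >= 5
  }, TRUE)
  expect_gte(mean(ext), 0.5)
})

test_that("positional and GC flags land on the planted confounders", {
  fx <- filter_fixture()
  cv <- fx$d$cnvrs
  tel <- fx$sim$truth$planted[2, ]
  i <- overlapping_row(cv, tel$chrom, tel$start, tel$end, tel$type)
  expect_true(any(grepl("telomere_centromere", cv$filter_flags[i])))
  gcr <- fx$sim$truth$planted[3, ]
  j <- overlapping_row(cv, gcr$chrom, gcr$start, gcr$end, gcr$type)
  expect_true(any(grepl("gc_extreme", cv$filter_flags[j])))
})

test_that("sample-bias flagging removes recurrent carriers and retests", {
  fx <- filter_fixture()
  cv <- fx$d$cnvrs
  for (k in seq_len(nrow(fx$sim$truth$bias_loci))) {
    b <- fx$sim$truth$bias_loci[k, ]
    i <- overlapping_row(cv, b$chrom, b$start, b$end, b$type)
    expect_true(any(grepl("sample_bias", cv$filter_flags[i])),
                label = paste("bias locus", k, "flagged"))
  }
  # the clean planted region keeps its signal: no bias flag
  clean <- fx$sim$truth$planted[1, ]
  j <- overlapping_row(cv, clean$chrom, clean$start, clean$end, clean$type)
  expect_false(grepl("sample_bias", cv$filter_flags[j]))
})

test_that("a region with ample independent carriers survives bias-sample removal", {
  # one sample sits in many regions, but each region has 30 other carriers
  n1 <- 500; n2 <- 500
  mk_region <- function(chrom, start, carriers) {
    data.frame(chrom = chrom, start = start, end = start + 1000L,
               type = "del", direction = "case_enriched",
               best_probe = "p", best_pos = start,
               p_discovery = fisher_exact_two_sided(length(carriers), 0,
                                                    n1, n2),
               case_carriers = length(carriers), control_carriers = 0L,
               n_probes_sig = 2L, filter_flags = "", genes = "",
               carriers_case = I(list(carriers)),
               carriers_control = I(list(character(0))),
               stringsAsFactors = FALSE)
  }
  rich <- do.call(rbind, lapply(1:5, function(k)
    mk_region("chr1", k * 100000L,
              c("BIAS1", sprintf("S%02d_%d", 1:30, k)))))
  fl <- flag_sample_bias(rich, n1, n2)
  expect_equal(fl, rep(list(character(0)), 5))

  # three-carrier regions driven by the same trio collapse on removal
  poor <- do.call(rbind, lapply(1:5, function(k)
    mk_region("chr1", k * 100000L, c("B1", "B2", "B3"))))
  fl2 <- flag_sample_bias(poor, n1, n2)
  expect_equal(fl2, rep(list("sample_bias"), 5))
})

test_that("filters are non-destructive and idempotent", {
  fx <- filter_fixture()
  d <- fx$d
  calls_qc <- fx$sim$calls[fx$sim$calls$sample_id %in%
                             d$samples$sample_id[d$samples$included], ]
  again <- apply_cnvr_filters(d$cnvrs, calls_qc, d$samples, d$probe_stats,
                              fx$sim$marker_map,
                              exclusion_track = fx$tracks$exclusion)
  expect_equal(again$filter_flags, d$cnvrs$filter_flags)
  expect_equal(again$p_discovery, d$cnvrs$p_discovery)
  expect_equal(again$case_carriers, d$cnvrs$case_carriers)
  expect_equal(nrow(again), nrow(d$cnvrs))
})
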