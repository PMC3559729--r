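test_that("significant probes chain across gaps up to 1 Mb and split beyond", {
  # 5 significant probes, a 2 Mb gap, then 4 more: two regions
  n_cases <- 500; n_controls <- 500
  pos <- c(1:5 * 10000L, 2.5e6 + 1:4 * 10000L)
  a <- rep(10L, 9); b <- rep(0L, 9)
  ps <- data.frame(probe_id = paste0("p", 1:9), chrom = "chr1",
                   pos = as.integer(pos), type = "del",
                   case_carriers = a, control_carriers = b,
                   n_cases = n_cases, n_controls = n_controls,
                   p = fisher_exact_two_sided(a, b, n_cases, n_controls),
                   enriched_in = "case", stringsAsFactors = FALSE)
  cv <- collapse_cnvrs(ps)
  expect_equal(nrow(cv), 2L)
  expect_equal(cv$start, as.integer(c(10000, 2.5e6 + 10000)))
  expect_equal(cv$end, as.integer(c(50000, 2.5e6 + 40000)))
  expect_equal(cv$n_probes_sig, c(5L, 4L))

  # an interleaved non-significant probe does not break the chain
  ps2 <- ps[1:5, ]
  ps2$case_carriers[3] <- 0L
  ps2$p[3] <- 1
  ps2$enriched_in[3] <- "neither"
  cv2 <- collapse_cnvrs(ps2)
  expect_equal(nrow(cv2), 1L)
  expect_equal(cv2$n_probes_sig, 4L)
})

test_that("regions below the minimum carrier count are dropped; best probe is leftmost minimum", {
  n1 <- 500; n2 <- 500
  mk <- function(a, b) {
    data.frame(probe_id = paste0("p", seq_along(a)), chrom = "chr1",
               pos = 10000L * seq_along(a), type = "del",
               case_carriers = a, control_carriers = b,
               n_cases = n1, n_controls = n2,
               p = fisher_exact_two_sided(a, b, n1, n2),
               enriched_in = ifelse(a / n1 > b / n2, "case",
                                    ifelse(b / n2 > a / n1, "control",
                                           "neither")),
               stringsAsFactors = FALSE)
  }
  # a nominally significant chain whose peak has only 2 carriers in the
  # enriched cohort is dropped (alpha relaxed so the chain forms at all)
  lax <- segmentation_params(alpha_probe = 0.6)
  cv <- collapse_cnvrs(mk(c(2L, 2L, 2L), c(0L, 0L, 0L)), lax)
  expect_equal(nrow(cv), 0L)
  cv_ok <- collapse_cnvrs(mk(c(3L, 3L, 3L), c(0L, 0L, 0L)), lax)
  expect_equal(nrow(cv_ok), 1L)
  expect_equal(cv_ok$case_carriers, 3L)

  # tie in p: leftmost probe wins
  ps3 <- mk(c(10L, 10L), c(0L, 0L))
  cv3 <- collapse_cnvrs(ps3)
  expect_equal(cv3$best_probe, "p1")

  expect_error(collapse_cnvrs(mk(c(10L, 10L), c(0L, 0L))[2:1, ]),
               "not sorted")
})

test_that("collapse matches the brute-force chain finder on random inputs", {
  # acceptance-grade equivalence runs 1000 vectors; this spot-checks 150
  set.seed(6)
  for (k in 1:150) {
    ps <- random_probe_stats(n_probes = 40)
    got <- collapse_cnvrs(ps)
    got <- got[order(got$chrom, got$start, got$type, got$direction), ]
    ref <- naive_collapse(ps)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$best_pos, ref$best_pos)
      expect_equal(got$p_discovery, ref$p_discovery)
    }
  }
})

test_that("every significant probe lies in exactly one region of its type and direction", {
  set.seed(7)
  for (k in 1:20) {
    ps <- random_probe_stats(n_probes = 80, seed = 100 + k)
    params <- segmentation_params(min_case_carriers = 0)
    cv <- collapse_cnvrs(ps, params)
    for (type in c("del", "dup")) for (dir in c("case", "control")) {
      sig <- ps[ps$type == type & ps$p < 0.05 & ps$enriched_in == dir, ]
      reg <- cv[cv$type == type & cv$direction == paste0(dir, "_enriched"), ]
      if (!nrow(sig)) { expect_equal(nrow(reg), 0L); next }
      hits <- vapply(sig$pos, function(p)
        sum(reg$start <= p & reg$end >= p), 1L)
      expect_true(all(hits == 1L))
      # no internal gap between consecutive significant probes exceeds 1 Mb
      for (i in seq_len(nrow(reg))) {
        inside <- sort(sig$pos[sig$pos >= reg$start[i] &
                                 sig$pos <= reg$end[i]])
        if (length(inside) > 1)
          expect_true(max(diff(inside)) <= params$max_gap_bp)
      }
    }
  }
})

test_that("segmentation is idempotent and chromosome-order independent", {
  ps1 <- random_probe_stats(n_probes = 50, seed = 11)
  ps2 <- random_probe_stats(n_probes = 50, seed = 12)
  ps2$chrom <- "chr2"
  ps2$probe_id <- paste0("c2_", ps2$probe_id)
  joint <- rbind(ps1, ps2)
  attr(joint, "n_cases") <- attr(ps1, "n_cases")
  swapped <- rbind(ps2, ps1)
  a <- collapse_cnvrs(joint)
  b <- collapse_cnvrs(swapped)
  key <- function(x) x[order(x$chrom, x$start, x$type, x$direction),
                       c("chrom", "start", "end", "type", "p_discovery")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  expect_equal(key(collapse_cnvrs(joint)), key(a), ignore_attr = TRUE)
})

test_that("effective test count merges overlapping del/dup regions", {
  del <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(100L, 5000L, 100L),
                    end = c(200L, 6000L, 200L), type = "del")
  dup <- data.frame(chrom = c("chr1", "chr3"),
                    start = c(150L, 1L), end = c(250L, 50L), type = "dup")
  # chr1:150-250 dup overlaps chr1:100-200 del -> counted once
  expect_equal(effective_test_count(del, dup), 4L)
  expect_equal(effective_test_count(del[2:3, ], dup[2, , drop = FALSE]), 3L)
  expect_equal(effective_test_count(del[0, ], dup[0, ]), 0L)
})

test_that("testable regions are runs of consecutive frequency-qualifying probes", {
  counts <- data.frame(
    probe_id = paste0("p", 1:10), chrom = "chr1", pos = 10000L * 1:10,
    type = "del",
    case_carriers = c(0L, 5L, 6L, 0L, 0L, 4L, 4L, 4L, 0L, 7L),
    control_carriers = 0L, stringsAsFactors = FALSE)
  attr(counts, "n_cases") <- 1000L
  # threshold 0.0015 * 1000 -> >= 2 carriers
  tr <- testable_regions(counts)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$start, c(20000L, 60000L, 100000L))
  expect_equal(tr$end, c(30000L, 80000L, 100000L))
})

test_that("the Bonferroni bar is alpha over the test count", {
  expect_equal(bonferroni_bar(1, 0.05), 0.05)
  expect_equal(bonferroni_bar(1000, 0.05), 5e-5)
  expect_error(bonferroni_bar(0), "positive")
})
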