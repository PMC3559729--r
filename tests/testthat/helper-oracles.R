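# Independent oracles and small fixture builders shared by the suite.
# Oracles deliberately avoid the code paths they check: the Fisher
# oracle enumerates tables with log-binomial coefficients (no dhyper),
# the chain oracle is a plain loop, the carrier oracle a per-probe scan.

# exhaustive minimum-likelihood two-sided Fisher p by table enumeration
enum_fisher_p <- function(a, b, N1, N2) {
  m <- a + b
  x <- max(0, m - N2):min(m, N1)
  logp <- lchoose(N1, x) + lchoose(N2, m - x) - lchoose(N1 + N2, m)
  prob <- exp(logp)
  obs <- prob[match(a, x)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# brute-force chain finder over one type/direction/chromosome at a time
naive_collapse <- function(probe_stats, alpha = 0.05, max_gap = 1e6,
                           min_carriers = 3) {
  rows <- list()
  for (type in c("del", "dup")) for (dir in c("case", "control")) {
    for (ch in unique(probe_stats$chrom)) {
      s <- probe_stats[probe_stats$type == type &
                         probe_stats$chrom == ch, , drop = FALSE]
      s <- s[order(s$pos), , drop = FALSE]
      sig <- s$p < alpha & s$enriched_in == dir
      i <- 1
      while (i <= nrow(s)) {
        if (!sig[i]) { i <- i + 1; next }
        members <- i
        j <- i + 1
        last <- i
        while (j <= nrow(s)) {
          if (sig[j]) {
            if (s$pos[j] - s$pos[last] > max_gap) break
            members <- c(members, j)
            last <- j
          }
          j <- j + 1
        }
        blk <- s[members, , drop = FALSE]
        best <- members[which.min(blk$p)]
        carr <- if (dir == "case") s$case_carriers[best]
                else s$control_carriers[best]
        if (carr >= min_carriers)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = ch, start = blk$pos[1], end = blk$pos[nrow(blk)],
            type = type, direction = paste0(dir, "_enriched"),
            best_pos = s$pos[best], p_discovery = s$p[best],
            stringsAsFactors = FALSE)
        i <- last + 1
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      direction = character(0), best_pos = integer(0),
                      p_discovery = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$type, out$direction), , drop = FALSE]
}

# per-probe carrier scan, one probe and sample at a time
naive_count_carriers <- function(calls, marker_map, samples, type) {
  inc <- if ("included" %in% names(samples))
    samples[samples$included, ] else samples
  ca <- integer(nrow(marker_map)); co <- integer(nrow(marker_map))
  for (i in seq_len(nrow(marker_map))) {
    ids <- character(0)
    for (j in seq_len(nrow(calls))) {
      if (calls$type[j] != type) next
      if (calls$chrom[j] != marker_map$chrom[i]) next
      if (calls$start[j] <= marker_map$pos[i] &&
          calls$end[j] >= marker_map$pos[i])
        ids <- c(ids, calls$sample_id[j])
    }
    ids <- unique(ids[ids %in% inc$sample_id])
    ca[i] <- sum(ids %in% inc$sample_id[inc$cohort == "case"])
    co[i] <- length(ids) - ca[i]
  }
  data.frame(pos = marker_map$pos, case_carriers = ca, control_carriers = co)
}

# hand step-up BH oracle
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# fixtures -------------------------------------------------------------

toy_map <- function(n = 50, chrom = "chr1", spacing = 10000, gc = 0.5) {
  data.frame(probe_id = sprintf("%s_p%03d", chrom, seq_len(n)),
             chrom = chrom, pos = spacing * seq_len(n),
             gc = rep_len(gc, n), stringsAsFactors = FALSE)
}

toy_samples <- function(n_cases, n_controls, n_pcs = 3) {
  n <- n_cases + n_controls
  s <- data.frame(
    sample_id = c(sprintf("CASE%04d", seq_len(n_cases)),
                  sprintf("CTRL%04d", seq_len(n_controls))),
    cohort = rep(c("case", "control"), c(n_cases, n_controls)),
    call_rate = 0.99, lrr_sd = 0.1, gcwf = 0.01, cnv_count = 1L,
    stringsAsFactors = FALSE)
  for (k in seq_len(n_pcs)) s[[paste0("PC", k)]] <- 0
  s$included <- TRUE
  s$exclusion_reason <- ""
  s
}

# a call covering probes [i1, i2] of a toy map
toy_call <- function(sample_id, map, i1, i2, state = 1L) {
  data.frame(sample_id = sample_id, chrom = map$chrom[i1],
             start = map$pos[i1], end = map$pos[i2],
             copy_state = as.integer(state), n_probes = i2 - i1 + 1L,
             type = if (state < 2) "del" else "dup",
             stringsAsFactors = FALSE)
}

# random probe-stat vector for segmentation property tests
random_probe_stats <- function(n_probes = 60, n_cases = 100,
                               n_controls = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- toy_map(n_probes, spacing = sample(c(10000, 300000, 700000), 1))
  one_type <- function(type) {
    a <- rpois(n_probes, 0.8) + rbinom(n_probes, 1, 0.15) * rpois(n_probes, 6)
    b <- rpois(n_probes, 0.8)
    a <- pmin(a, n_cases); b <- pmin(b, n_controls)
    p <- cnvscan::fisher_exact_two_sided(a, b, n_cases, n_controls)
    fa <- a / n_cases; fb <- b / n_controls
    data.frame(probe_id = paste0(map$probe_id, "_", type),
               chrom = map$chrom, pos = map$pos, type = type,
               case_carriers = a, control_carriers = b,
               n_cases = n_cases, n_controls = n_controls, p = p,
               enriched_in = ifelse(fa > fb, "case",
                                    ifelse(fb > fa, "control", "neither")),
               stringsAsFactors = FALSE)
  }
  ps <- rbind(one_type("del"), one_type("dup"))
  attr(ps, "n_cases") <- n_cases
  attr(ps, "n_controls") <- n_controls
  ps
}
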