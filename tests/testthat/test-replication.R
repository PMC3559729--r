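test_that("logistic association matches glm() and collapses to the covariate-free model", {
  set.seed(8)
  n <- 400
  pcs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  carrier <- rbinom(n, 1, 0.15)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * carrier + 0.5 * pcs[, 1]))
  cohort <- ifelse(y == 1, "case", "control")

  fit <- logistic_cnv_association(carrier, cohort, pcs)
  ref <- stats::glm(y ~ carrier + pcs, family = binomial())
  expect_false(fit$separation_detected)
  expect_equal(fit$beta_cnv, unname(coef(ref)["carrier"]), tolerance = 1e-8)
  expect_equal(fit$p, summary(ref)$coefficients["carrier", 4],
               tolerance = 1e-8)
  expect_equal(fit$covariates_used, 1:3)

  # zero-variance PCs reproduce the covariate-free coefficient
  flat <- matrix(1.7, n, 3)
  fit0 <- logistic_cnv_association(carrier, cohort)
  fitf <- logistic_cnv_association(carrier, cohort, flat)
  expect_equal(fitf$beta_cnv, fit0$beta_cnv, tolerance = 1e-6)
  expect_equal(fitf$covariates_used, integer(0))

  # Wald and likelihood-ratio p agree within a factor of two here
  fit_lrt <- logistic_cnv_association(carrier, cohort, pcs, test = "lrt")
  expect_lt(abs(log(fit$p / fit_lrt$p)), log(2))

  expect_error(logistic_cnv_association(rep(1, n), cohort), "degenerate")
})

test_that("separation is detected and the Firth fallback stays finite", {
  # all carriers in cases, none in controls: quasi-complete separation
  carrier <- c(rep(1, 12), rep(0, 188), rep(0, 200))
  cohort <- rep(c("case", "control"), each = 200)
  fit <- logistic_cnv_association(carrier, cohort)
  expect_true(fit$separation_detected)
  expect_true(fit$converged)
  expect_true(is.finite(fit$beta_cnv) && is.finite(fit$se))
  expect_gt(fit$beta_cnv, 0)  # case-enriched
  expect_lt(fit$p, 0.05)
  expect_equal(fit$method, "firth_wald")

  # Firth agrees with ML closely away from separation
  set.seed(9)
  n <- 600
  x <- cbind(1, rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-0.2 + 1.0 * x[, 2]))
  firth <- cnvscan:::firth_logistic(x, y)
  ml <- stats::glm(y ~ x[, 2], family = binomial())
  expect_equal(firth$coefficients[2], unname(coef(ml)[2]), tolerance = 0.05)
})

test_that("replication p-values are uniform when carrier status is independent of cohort", {
  set.seed(10)
  n <- 600
  pcs <- matrix(rnorm(n * 3), n, 3)
  cohort <- rep(c("case", "control"), each = n / 2)
  p <- replicate(300, {
    carrier <- rbinom(n, 1, 0.1)
    logistic_cnv_association(carrier, cohort, pcs)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.05)
})

test_that("the score-test scan agrees with Pearson chi-square and the Wald fit", {
  set.seed(12)
  n <- 500
  cohort <- rep(c("case", "control"), each = n / 2)
  carrier <- matrix(rbinom(n * 20, 1, 0.2), n, 20)
  p_scan <- inflation_scan(carrier, cohort)
  # with no covariates the score test is the Pearson chi-square test
  p_ref <- apply(carrier, 2, function(x)
    suppressWarnings(stats::chisq.test(table(x, cohort),
                                       correct = FALSE)$p.value))
  expect_equal(p_scan, unname(p_ref), tolerance = 1e-8)

  pcs <- matrix(rnorm(n * 3), n, 3)
  p_cov <- inflation_scan(carrier, cohort, pcs)
  p_wald <- apply(carrier, 2, function(x)
    logistic_cnv_association(x, cohort, pcs)$p)
  expect_equal(-log10(p_cov), -log10(unname(p_wald)), tolerance = 0.05)

  # constant columns are NA
  carrier0 <- cbind(carrier[, 1:2], 0)
  expect_true(is.na(inflation_scan(carrier0, cohort)[3]))
})

test_that("genomic inflation is 1 at the null median and errors on bad input", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1.0, tolerance = 1e-12)
  set.seed(13)
  expect_equal(genomic_inflation(runif(10000)), 1.0, tolerance = 0.05)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Fisher's method follows the 2k-df chi-square identity", {
  c1 <- fisher_combine(c(1, 1))
  expect_equal(c1$chi_sq, 0)
  expect_equal(c1$df, 4L)
  expect_equal(c1$p_combined, 1)

  c2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(c2$chi_sq, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(c2$chi_sq, 11.98, tolerance = 1e-3)
  expect_equal(c2$p_combined,
               stats::pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(c2$p_combined, 0.017479, tolerance = 1e-4)

  # a single p-value combines to itself (2-df identity)
  for (p in c(0.9, 0.3, 1e-5))
    expect_equal(fisher_combine(p)$p_combined, p, tolerance = 1e-12)

  # permutation invariance and monotonicity
  expect_equal(fisher_combine(c(0.01, 0.4, 0.7))$p_combined,
               fisher_combine(c(0.7, 0.01, 0.4))$p_combined)
  expect_lt(fisher_combine(c(0.01, 0.2))$p_combined,
            fisher_combine(c(0.02, 0.2))$p_combined)

  expect_error(fisher_combine(c(0.5, 0)), "floor")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})
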