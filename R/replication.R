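## Replication-stage statistics: logistic association of case/control
## status on carrier state with principal-component covariates absorbing
## residual population structure, the genomic inflation factor as a
## stratification diagnostic, and Fisher's method for combining
## discovery and replication p-values.

## internal: Firth-penalised logistic regression (Jeffreys prior).
## The score is corrected with hat-matrix diagonals, which keeps the
## estimate finite under complete or quasi-complete separation — the
## usual situation for rare CNVs with zero carriers in one cohort.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(info_inv %*% U)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))  # damped step
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  se <- sqrt(diag(info_inv))
  list(coefficients = beta, se = se, converged = converged)
}

#' PC-corrected logistic CNV association
#'
#' Maximum-likelihood logistic regression of case/control status on
#' carrier state plus principal-component covariates (by default the
#' first three supplied), with a two-sided Wald test on the carrier
#' coefficient. Complete or quasi-complete separation on carrier state
#' (a zero cell in the carrier-by-cohort table) is detected and handled
#' with a Firth-penalised fit; this is reported, never silent.
#'
#' @param carrier per-sample 0/1 carrier status.
#' @param cohort per-sample `"case"`/`"control"` label.
#' @param pcs matrix or data frame of principal-component covariates
#'   aligned with `carrier`, or `NULL` for no correction. Zero-variance
#'   columns are dropped, so constant PCs reproduce the covariate-free
#'   model.
#' @param test `"wald"` (default) or `"lrt"` for a likelihood-ratio
#'   p-value on the carrier term (maximum-likelihood fits only).
#' @return list with `beta_cnv` (log-odds for carrier state), `se`,
#'   `p`, `converged`, `separation_detected`, `covariates_used`,
#'   `method`.
#' @export
logistic_cnv_association <- function(carrier, cohort, pcs = NULL,
                                     test = c("wald", "lrt")) {
  test <- match.arg(test)
  carrier <- as.integer(carrier)
  if (length(carrier) != length(cohort))
    stop("carrier and cohort must be aligned")
  if (!all(cohort %in% c("case", "control")))
    stop("cohort must be 'case' or 'control'")
  y <- as.integer(cohort == "case")
  if (all(carrier == 1) || all(carrier == 0))
    stop("degenerate input: carrier status is constant")
  covariates_used <- integer(0)
  X <- cbind(`(Intercept)` = 1, carrier = carrier)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != length(carrier)) stop("pcs not aligned with carrier")
    keep <- apply(pcs, 2, function(v) stats::sd(v) > 0)
    if (any(keep)) {
      covariates_used <- unname(which(keep))
      pk <- pcs[, keep, drop = FALSE]
      colnames(pk) <- paste0("PC", covariates_used)
      X <- cbind(X, pk)
    }
  }
  tab <- table(factor(carrier, c(0, 1)), factor(y, c(0, 1)))
  separation <- any(tab == 0)

  if (separation) {
    fit <- firth_logistic(X, y)
    beta <- fit$coefficients[2]; se <- fit$se[2]
    p <- 2 * stats::pnorm(-abs(beta / se))
    return(list(beta_cnv = unname(beta), se = unname(se), p = p,
                converged = fit$converged, separation_detected = TRUE,
                covariates_used = covariates_used, method = "firth_wald"))
  }

  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients["carrier"]
  w <- fit$weights
  se <- sqrt(diag(solve(crossprod(X * sqrt(w)))))[2]
  if (test == "wald") {
    p <- 2 * stats::pnorm(-abs(beta / se))
    method <- "ml_wald"
  } else {
    X0 <- X[, -2, drop = FALSE]
    fit0 <- suppressWarnings(stats::glm.fit(X0, y,
                                            family = stats::binomial()))
    p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
    method <- "ml_lrt"
  }
  list(beta_cnv = unname(beta), se = unname(se), p = unname(p),
       converged = fit$converged, separation_detected = FALSE,
       covariates_used = covariates_used, method = method)
}

#' Genome-wide score-test association scan
#'
#' Rao score test of the carrier term at the covariate-only null, for a
#' whole matrix of loci at once: the null logistic model (intercept plus
#' any PC covariates) is fitted once, and each locus costs one pass over
#' the samples. This is the workhorse behind genomic-inflation
#' diagnostics, where thousands of per-locus p-values are needed and a
#' per-locus maximum-likelihood fit would be wasteful; per-locus
#' estimates for reporting come from [logistic_cnv_association()].
#'
#' @param carrier samples-by-loci 0/1 matrix of carrier status.
#' @param cohort per-sample `"case"`/`"control"` label.
#' @param pcs optional matrix of PC covariates.
#' @return vector of score-test p-values, one per locus (`NA` for loci
#'   with constant carrier status).
#' @export
inflation_scan <- function(carrier, cohort, pcs = NULL) {
  carrier <- as.matrix(carrier) * 1
  y <- as.integer(cohort == "case")
  n <- length(y)
  if (nrow(carrier) != n) stop("carrier matrix not aligned with cohort")
  X0 <- cbind(rep(1, n), if (!is.null(pcs)) as.matrix(pcs))
  fit <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  A_inv <- solve(crossprod(X0 * sqrt(w)))
  U <- drop(crossprod(carrier, y - mu))
  M <- crossprod(carrier * w, X0)
  V <- drop(crossprod(carrier, w)) - rowSums((M %*% A_inv) * M)
  p <- stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
  cs <- colSums(carrier)
  p[cs == 0 | cs == n] <- NA_real_
  p
}

#' Genomic inflation factor
#'
#' `lambda` is the median of the observed 1-df association chi-squares
#' (obtained from p-values by inverse survival) divided by the null
#' median 0.4549; `lambda` near 1 indicates controlled population
#' stratification.
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @return the inflation factor, a positive scalar.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Combine p-values with Fisher's method
#'
#' `X^2 = -2 * sum(log(p_i))` follows a chi-square distribution with
#' `2k` degrees of freedom under the joint null; the combined p-value is
#' its upper tail. For two studies this is a 4-df chi-square. A zero
#' p-value is an error (its log is undefined); callers must floor such
#' values first.
#'
#' @param p_list vector of independent p-values in `(0, 1]`.
#' @return object of class `combined_p`: list with `p_list`, `chi_sq`,
#'   `df` and `p_combined`.
#' @export
fisher_combine <- function(p_list) {
  p_list <- as.numeric(p_list)
  if (!length(p_list)) stop("no p-values supplied")
  if (any(is.na(p_list))) stop("NA p-value")
  if (any(p_list <= 0))
    stop("p-value of 0 supplied; floor at the smallest positive value first")
  if (any(p_list > 1)) stop("p-values must lie in (0, 1]")
  chi_sq <- -2 * sum(log(p_list))
  df <- 2L * length(p_list)
  structure(list(p_list = p_list, chi_sq = chi_sq, df = df,
                 p_combined = stats::pchisq(chi_sq, df = df,
                                            lower.tail = FALSE)),
            class = "combined_p")
}

#' @export
print.combined_p <- function(x, ...) {
  cat(sprintf("Fisher's method: X^2 = %.4g on %d df, combined p = %.4g\n",
              x$chi_sq, x$df, x$p_combined))
  invisible(x)
}
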