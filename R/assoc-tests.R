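# The six association tests for H0: theta2 = 0 in
#   logit Pr(Y = 1) = b0 + be'E + theta2' X2,   X2 = G or (G, G*E).
#
# All score statistics are quadratic forms U' C^{-1} U where U is an
# (unnormalized) sum of per-individual score contributions and C is a
# Schur complement of weighted cross-product sums; the 1/n and 1/sqrt(n)
# factors of the scaled formulation cancel and are therefore never
# materialized (unit-tested against the scaled assembly).
#
# CST  refits the null on the complete-case subset of each SNP:
#        U  = sum_i I_i X2i (y_i - pi_i(th1m)),
#        C  = S22m - S21m S11m^{-1} S12m  at th1m.
# PM1  reuses the global null fit th1f (all n individuals, no genotype)
#      and replaces the middle block with the FULL-sample information:
#        C  = S22m - S21m S11f^{-1} S12m  at th1f.
#      The asymmetry (m outer blocks, full middle block) is intentional
#      and is what costs PM1 power when genotypes are missing.
# PM2  orthogonalizes the per-individual genotype score against the
#      nuisance score (efficient score),
#        u2i* = u2im - S21m S11m^{-1} u1im  at th1f,
#      and uses the complete-case-form variance, making it asymptotically
#      equivalent to CST while still needing only the single global fit.

# Schur complement of the weighted cross products; NULL when the nuisance
# block is numerically singular.
schur_complement <- function(S22, S12, S11) {
  sol <- tryCatch(solve(S11, S12), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  S22 - crossprod(S12, sol)
}

# U' C^{-1} U, or NULL when C is singular/indefinite.
quad_form <- function(U, C) {
  if (is.null(C)) return(NULL)
  if (rcond(C) < 1e-12) return(NULL)
  val <- tryCatch(drop(crossprod(U, solve(C, U))), error = function(e) NULL)
  if (is.null(val) || !is.finite(val) || val < 0) return(NULL)
  val
}

observed_monomorphic <- function(g) {
  length(unique(g$codes[!is.na(g$codes)])) < 2L
}

check_g <- function(g) {
  if (g$n_obs == 0L) stop("all genotypes are missing")
}

#' Conventional score test (per-SNP complete-case null fit)
#'
#' Refits the null model on the subset of individuals with an observed
#' genotype, then forms the score statistic from the missing-weighted
#' score and information blocks at that subset-specific null MLE. This is
#' the reference complete-case analysis; it requires one iterative fit per
#' SNP.
#'
#' @param dataset A [case_control_dataset()].
#' @param g A [genotype_vector()].
#' @param terms A [term_spec()].
#' @return An `assoc_test_result`.
#' @export
cst_test <- function(dataset, g, terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("CST", NA_real_, terms$df, dataset$n, g$n_obs,
                       "monomorphic"))
  }
  sub <- which(g$mask == 1)
  ys <- dataset$y[sub]
  if (all(ys == ys[1])) {
    return(test_result("CST", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  X1 <- build_x1(dataset)
  fit <- fit_logistic_mle(dataset$y, X1, subset = sub)
  if (!fit$converged) {
    return(test_result("CST", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  X2 <- build_x2(dataset, g, terms)
  rb <- raw_blocks(dataset$y, X1, X2, fit$theta, g$mask)
  C <- schur_complement(rb$S22, rb$S12, rb$S11)
  stat <- quad_form(rb$u2, C)
  if (is.null(stat)) {
    return(test_result("CST", NA_real_, terms$df, dataset$n, g$n_obs,
                       "degenerate_variance"))
  }
  test_result("CST", stat, terms$df, dataset$n, g$n_obs)
}

#' Fast score test with a single global null fit (PM1)
#'
#' Uses the global null MLE fitted once on all individuals (genotypes
#' never enter the null model, so the fit is shared across every SNP in a
#' scan). The variance combines missing-weighted outer blocks with the
#' full-sample nuisance information in the middle; this is cheap but
#' inflates the variance under missingness, so PM1 is asymptotically less
#' powerful than [pm2_test()] / [cst_test()].
#'
#' @param global_null A `logistic_fit` of the null model on all `n`
#'   individuals (it is NOT refit here).
#' @inheritParams cst_test
#' @return An `assoc_test_result`.
#' @export
pm1_test <- function(global_null, dataset, g, terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("PM1", NA_real_, terms$df, dataset$n, g$n_obs,
                       "monomorphic"))
  }
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  rbm <- raw_blocks(dataset$y, X1, X2, global_null$theta, g$mask)
  S11f <- crossprod(X1, X1 * (rbm$weights))   # full-sample nuisance block
  C <- schur_complement(rbm$S22, rbm$S12, S11f)
  stat <- quad_form(rbm$u2, C)
  if (is.null(stat)) {
    return(test_result("PM1", NA_real_, terms$df, dataset$n, g$n_obs,
                       "degenerate_variance"))
  }
  test_result("PM1", stat, terms$df, dataset$n, g$n_obs)
}

#' Per-individual efficient-score contributions
#'
#' Projects the genotype score contribution of each individual onto the
#' orthogonal complement of the nuisance (intercept + covariate) score,
#' using the missing-weighted information blocks evaluated at the global
#' null fit:
#' `u2i* = u2im - S21m S11m^{-1} u1im`.
#' Individuals with a missing genotype contribute a zero row.
#'
#' @inheritParams pm1_test
#' @return An `n x df` matrix of per-individual contributions.
#' @export
efficient_score_contributions <- function(global_null, dataset, g,
                                          terms = term_spec("g")) {
  check_g(g)
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  rbm <- raw_blocks(dataset$y, X1, X2, global_null$theta, g$mask)
  Bt <- tryCatch(solve(rbm$S11, rbm$S12), error = function(e) NULL)  # p1 x p2
  if (is.null(Bt)) {
    stop("singular nuisance information block among observed individuals")
  }
  rbm$per_u2 - rbm$per_u1 %*% Bt
}

#' Efficient-score test with a single global null fit (PM2)
#'
#' Sums the efficient-score contributions of
#' [efficient_score_contributions()] and compares the quadratic form
#' against the complete-case-form variance, with every block evaluated at
#' the global null fit. Asymptotically equivalent to [cst_test()] while
#' sharing PM1's single-fit cost structure.
#'
#' @inheritParams pm1_test
#' @return An `assoc_test_result`.
#' @export
pm2_test <- function(global_null, dataset, g, terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("PM2", NA_real_, terms$df, dataset$n, g$n_obs,
                       "monomorphic"))
  }
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  rbm <- raw_blocks(dataset$y, X1, X2, global_null$theta, g$mask)
  Bt <- tryCatch(solve(rbm$S11, rbm$S12), error = function(e) NULL)
  if (is.null(Bt)) {
    return(test_result("PM2", NA_real_, terms$df, dataset$n, g$n_obs,
                       "degenerate_variance"))
  }
  Ustar <- rbm$u2 - drop(crossprod(Bt, rbm$u1))
  C <- schur_complement(rbm$S22, rbm$S12, rbm$S11)
  stat <- quad_form(Ustar, C)
  if (is.null(stat)) {
    return(test_result("PM2", NA_real_, terms$df, dataset$n, g$n_obs,
                       "degenerate_variance"))
  }
  test_result("PM2", stat, terms$df, dataset$n, g$n_obs)
}

#' Wald test on the complete-case subset
#'
#' Fits the full model (null design plus the tested genotype terms) on the
#' complete-case subset and forms `theta2' var(theta2)^{-1} theta2` from
#' the inverse observed information.
#'
#' @inheritParams cst_test
#' @return An `assoc_test_result`.
#' @export
wald_test <- function(dataset, g, terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("WALD", NA_real_, terms$df, dataset$n, g$n_obs,
                       "monomorphic"))
  }
  sub <- which(g$mask == 1)
  ys <- dataset$y[sub]
  if (all(ys == ys[1])) {
    return(test_result("WALD", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  Xfull <- cbind(X1, X2)
  fit <- tryCatch(fit_logistic_mle(dataset$y, Xfull, subset = sub),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$separation || is.null(fit$vcov)) {
    return(test_result("WALD", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  idx2 <- ncol(X1) + seq_len(terms$df)
  th2 <- fit$theta[idx2]
  V22 <- fit$vcov[idx2, idx2, drop = FALSE]
  stat <- quad_form(th2, V22)
  # quad_form inverts V22: W = th2' V22^{-1} th2
  if (is.null(stat)) {
    return(test_result("WALD", NA_real_, terms$df, dataset$n, g$n_obs,
                       "degenerate_variance"))
  }
  test_result("WALD", stat, terms$df, dataset$n, g$n_obs)
}

#' Likelihood-ratio test on the complete-case subset
#'
#' Twice the log-likelihood gap between the full-model and null-model MLEs
#' fitted on the same complete-case subset; truncated at zero to absorb
#' optimizer round-off.
#'
#' @inheritParams cst_test
#' @return An `assoc_test_result`.
#' @export
lrt_test <- function(dataset, g, terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("LRT", NA_real_, terms$df, dataset$n, g$n_obs,
                       "monomorphic"))
  }
  sub <- which(g$mask == 1)
  ys <- dataset$y[sub]
  if (all(ys == ys[1])) {
    return(test_result("LRT", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  fit0 <- tryCatch(fit_logistic_mle(dataset$y, X1, subset = sub),
                   error = function(e) NULL)
  fit1 <- tryCatch(fit_logistic_mle(dataset$y, cbind(X1, X2), subset = sub),
                   error = function(e) NULL)
  ok <- !is.null(fit0) && !is.null(fit1) && fit0$converged && fit1$converged &&
    !fit1$separation
  if (!ok) {
    return(test_result("LRT", NA_real_, terms$df, dataset$n, g$n_obs,
                       "not_converged"))
  }
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  test_result("LRT", stat, terms$df, dataset$n, g$n_obs)
}

#' Median-imputation score test
#'
#' Replaces missing genotype codes by the median of the observed codes,
#' rounded onto the 0/1/2 lattice (half-integer medians round down, so
#' 0.5 -> 0 and 1.5 -> 1), then applies the complete-data score test at
#' the global null fit.
#'
#' @inheritParams pm1_test
#' @return An `assoc_test_result`.
#' @export
median_impute_test <- function(global_null, dataset, g,
                               terms = term_spec("g")) {
  check_g(g)
  if (observed_monomorphic(g)) {
    return(test_result("MEDIAN_IMPUTE", NA_real_, terms$df, dataset$n,
                       g$n_obs, "monomorphic"))
  }
  med <- stats::median(g$codes[!is.na(g$codes)])
  fill <- floor(med + 0.5 - .Machine$double.eps^0.5)  # 0.5 -> 0, 1.5 -> 1
  if (!fill %in% c(0, 1, 2)) fill <- round(med)
  codes <- ifelse(is.na(g$codes), fill, g$codes)
  g_imp <- genotype_vector(codes, marker = g$marker)

  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g_imp, terms)
  rb <- raw_blocks(dataset$y, X1, X2, global_null$theta, rep(1, dataset$n))
  C <- schur_complement(rb$S22, rb$S12, rb$S11)
  stat <- quad_form(rb$u2, C)
  if (is.null(stat)) {
    return(test_result("MEDIAN_IMPUTE", NA_real_, terms$df, dataset$n,
                       g$n_obs, "degenerate_variance"))
  }
  test_result("MEDIAN_IMPUTE", stat, terms$df, dataset$n, g$n_obs)
}

#' Run one association test by method tag
#'
#' Dispatcher used by the genome scan and the simulation harness.
#'
#' @param method One of `"cst"`, `"pm1"`, `"pm2"`, `"wald"`, `"lrt"`,
#'   `"median"` (case-insensitive).
#' @param global_null Global null fit; required for `pm1`, `pm2` and
#'   `median`.
#' @inheritParams cst_test
#' @return An `assoc_test_result`.
#' @export
run_test <- function(method, dataset, g, terms = term_spec("g"),
                     global_null = NULL) {
  m <- tolower(method)
  needs_null <- m %in% c("pm1", "pm2", "median")
  if (needs_null && is.null(global_null)) {
    stop("method '", method, "' requires the global null fit")
  }
  switch(m,
    cst = cst_test(dataset, g, terms),
    pm1 = pm1_test(global_null, dataset, g, terms),
    pm2 = pm2_test(global_null, dataset, g, terms),
    wald = wald_test(dataset, g, terms),
    lrt = lrt_test(dataset, g, terms),
    median = median_impute_test(global_null, dataset, g, terms),
    stop("unknown method: ", method)
  )
}
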