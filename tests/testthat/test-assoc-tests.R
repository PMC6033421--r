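# The six association tests against formula/optimizer oracles, plus the
# structural identities that define the fast methods.

tt_fixture <- function() {
  list(d = fixture12_dataset(), g = fixture12_genotype(), f = fixture12())
}

global_fit <- function(d) fit_logistic_mle(d$y, cbind(1, d$E))

test_that("statistics on the fixture match independent oracles to 1e-5", {
  x <- tt_fixture()
  gn <- global_fit(x$d)
  checks <- list(
    cst = list(got = cst_test(x$d, x$g), want = oracle_cst(x$f$y, x$f$E, x$f$G)),
    pm1 = list(got = pm1_test(gn, x$d, x$g), want = oracle_pm1(x$f$y, x$f$E, x$f$G)),
    pm2 = list(got = pm2_test(gn, x$d, x$g), want = oracle_pm2(x$f$y, x$f$E, x$f$G)),
    wald = list(got = wald_test(x$d, x$g), want = oracle_wald(x$f$y, x$f$E, x$f$G)),
    lrt = list(got = lrt_test(x$d, x$g), want = oracle_lrt(x$f$y, x$f$E, x$f$G))
  )
  for (nm in names(checks)) {
    res <- checks[[nm]]$got
    expect_identical(res$status, "ok")
    expect_equal(res$statistic, checks[[nm]]$want, tolerance = 1e-5,
                 label = paste(nm, "statistic"))
    expect_equal(res$p_value,
                 pchisq(res$statistic, res$df, lower.tail = FALSE))
  }
  # PM1 genuinely differs from CST on data with missing genotypes
  expect_gt(abs(checks$pm1$got$statistic - checks$cst$got$statistic), 1e-4)
})

test_that("larger random fixtures (n <= 50) also match the oracles", {
  set.seed(97)
  for (k in 1:3) {
    n <- 50
    E <- rbinom(n, 1, 0.5)
    G <- rbinom(n, 2, 0.3)
    G[sample(n, 8)] <- NA
    y <- rbinom(n, 1, plogis(-0.2 + 0.3 * E))
    if (length(unique(y[!is.na(G)])) < 2) next
    d <- case_control_dataset(y, matrix(E, ncol = 1))
    g <- genotype_vector(G)
    gn <- global_fit(d)
    expect_equal(cst_test(d, g)$statistic, oracle_cst(y, E, G),
                 tolerance = 1e-5)
    expect_equal(pm1_test(gn, d, g)$statistic, oracle_pm1(y, E, G),
                 tolerance = 1e-5)
    expect_equal(pm2_test(gn, d, g)$statistic, oracle_pm2(y, E, G),
                 tolerance = 1e-5)
    expect_equal(wald_test(d, g)$statistic, oracle_wald(y, E, G),
                 tolerance = 1e-5)
    expect_equal(lrt_test(d, g)$statistic, oracle_lrt(y, E, G),
                 tolerance = 1e-4)
  }
})

test_that("with no missing genotypes CST, PM1 and PM2 coincide", {
  set.seed(13)
  for (k in 1:20) {
    n <- 80
    E <- rbinom(n, 1, 0.5)
    G <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2 || length(unique(G)) < 2) next
    d <- case_control_dataset(y, matrix(E, ncol = 1))
    g <- genotype_vector(G)
    gn <- global_fit(d)
    s_cst <- cst_test(d, g)$statistic
    expect_equal(pm1_test(gn, d, g)$statistic, s_cst, tolerance = 1e-10)
    expect_equal(pm2_test(gn, d, g)$statistic, s_cst, tolerance = 1e-10)
    expect_equal(median_impute_test(gn, d, g)$statistic, s_cst,
                 tolerance = 1e-10)
  }
})

test_that("efficient-score contributions follow the projection formula", {
  x <- tt_fixture()
  gn <- global_fit(x$d)
  U <- efficient_score_contributions(gn, x$d, x$g)
  expect_equal(dim(U), c(12L, 1L))
  # rows with missing genotype contribute exactly zero
  expect_true(all(U[is.na(x$f$G), ] == 0))
  # element-wise assembly from numerically derived blocks
  ob <- oracle_blocks(x$f$y, cbind(1, x$f$E),
                      matrix(ifelse(is.na(x$f$G), 0, x$f$G), ncol = 1),
                      unname(gn$theta), x$g$mask)
  p <- plogis(drop(cbind(1, x$f$E) %*% gn$theta))
  r <- (x$f$y - p) * x$g$mask
  want <- matrix(ifelse(is.na(x$f$G), 0, x$f$G) * r, ncol = 1) -
    (cbind(1, x$f$E) * r) %*% (solve(ob$J11) %*% ob$J12)
  expect_equal(unname(U), unname(want), tolerance = 1e-5)

  # with no missing the column sums reduce to the raw genotype score
  g_complete <- genotype_vector(ifelse(is.na(x$f$G), 1, x$f$G))
  U2 <- efficient_score_contributions(gn, x$d, g_complete)
  sb <- score_blocks(gn, x$d, g_complete)
  expect_equal(unname(colSums(U2)), unname(sb$u2), tolerance = 1e-7)
})

test_that("statistics are permutation invariant", {
  x <- tt_fixture()
  set.seed(5)
  ord <- sample(12)
  d2 <- case_control_dataset(x$f$y[ord], matrix(x$f$E[ord], ncol = 1))
  g2 <- genotype_vector(x$f$G[ord])
  gn <- global_fit(x$d)
  gn2 <- global_fit(d2)
  for (fn in list(function(d, g, n) cst_test(d, g),
                  function(d, g, n) pm1_test(n, d, g),
                  function(d, g, n) pm2_test(n, d, g))) {
    expect_equal(fn(x$d, x$g, gn)$statistic, fn(d2, g2, gn2)$statistic,
                 tolerance = 1e-9)
  }
})

test_that("allele-coding flips leave CST/PM2/Wald/LRT/median unchanged; PM1 is the exception", {
  set.seed(31)
  n <- 200
  E <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.2 + 0.2 * E))
  G <- rbinom(n, 2, 0.3)
  G[sample(n, 40)] <- NA
  d <- case_control_dataset(y, matrix(E, ncol = 1))
  g <- genotype_vector(G)
  gflip <- genotype_vector(2 - G)
  gn <- global_fit(d)
  expect_equal(cst_test(d, g)$statistic, cst_test(d, gflip)$statistic,
               tolerance = 1e-8)
  expect_equal(pm2_test(gn, d, g)$statistic,
               pm2_test(gn, d, gflip)$statistic, tolerance = 1e-8)
  expect_equal(wald_test(d, g)$statistic, wald_test(d, gflip)$statistic,
               tolerance = 1e-6)
  expect_equal(lrt_test(d, g)$statistic, lrt_test(d, gflip)$statistic,
               tolerance = 1e-8)
  expect_equal(median_impute_test(gn, d, g)$statistic,
               median_impute_test(gn, d, gflip)$statistic,
               tolerance = 1e-8)
  # PM1's variance mixes missing-weighted outer blocks with the full-sample
  # middle block, so its quadratic form is NOT a projection and the
  # statistic depends on which allele is counted (documented limitation).
  expect_gt(abs(pm1_test(gn, d, g)$statistic -
                  pm1_test(gn, d, gflip)$statistic), 1e-6)
})

test_that("monomorphic and degenerate inputs yield typed statuses", {
  x <- tt_fixture()
  gn <- global_fit(x$d)
  g_const <- genotype_vector(rep(1, 12))
  for (res in list(cst_test(x$d, g_const), pm1_test(gn, x$d, g_const),
                   pm2_test(gn, x$d, g_const), wald_test(x$d, g_const),
                   lrt_test(x$d, g_const),
                   median_impute_test(gn, x$d, g_const))) {
    expect_identical(res$status, "monomorphic")
    expect_true(is.na(res$p_value))
  }
  # observed-constant after masking counts as monomorphic too
  g_m <- genotype_vector(c(1, 1, 1, NA, 1, 1, 1, NA, 1, 1, NA, 1))
  expect_identical(cst_test(x$d, g_m)$status, "monomorphic")
  expect_error(cst_test(x$d, genotype_vector(rep(NA_real_, 12))), "missing")
})

test_that("median imputation fills the documented lattice values", {
  x <- tt_fixture()
  gn <- global_fit(x$d)
  # median of {0,1,2} = 1
  g <- genotype_vector(c(0, 1, NA, 2, NA, rep(1, 7)))
  res <- median_impute_test(gn, x$d, g)
  expect_identical(res$status, "ok")
  # half-integer medians round down: median of {0,0,1,1} = 0.5 -> 0
  g2 <- genotype_vector(c(0, 0, 1, 1, rep(NA, 8)))
  d2 <- x$d
  # verify via the imputed statistic equalling the statistic of the
  # hand-imputed complete vector
  filled <- c(0, 0, 1, 1, rep(0, 8))
  expect_equal(median_impute_test(gn, d2, g2)$statistic,
               median_impute_test(gn, d2, genotype_vector(filled))$statistic,
               tolerance = 1e-12)
  # median 1.5 -> 1
  g3 <- genotype_vector(c(1, 1, 2, 2, rep(NA, 8)))
  filled3 <- c(1, 1, 2, 2, rep(1, 8))
  expect_equal(median_impute_test(gn, x$d, g3)$statistic,
               median_impute_test(gn, x$d, genotype_vector(filled3))$statistic,
               tolerance = 1e-12)
})

test_that("LRT is non-negative across a random sweep", {
  set.seed(77)
  worst <- Inf
  for (k in 1:300) {
    n <- 24
    E <- rbinom(n, 1, 0.5)
    G <- rbinom(n, 2, 0.3)
    G[runif(n) < 0.15] <- NA
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y[!is.na(G)])) < 2 ||
        length(unique(G[!is.na(G)])) < 2) next
    d <- case_control_dataset(y, matrix(E, ncol = 1))
    res <- lrt_test(d, genotype_vector(G))
    if (identical(res$status, "ok")) {
      expect_gte(res$statistic, 0)
      worst <- min(worst, res$statistic)
    }
  }
  expect_true(is.finite(worst))
})

test_that("joint 2-df gene-environment test matches its oracle", {
  set.seed(303)
  n <- 50
  E <- rbinom(n, 1, 0.5)
  G <- rbinom(n, 2, 0.4)
  G[sample(n, 6)] <- NA
  y <- rbinom(n, 1, plogis(-0.1 + 0.3 * E))
  d <- case_control_dataset(y, matrix(E, ncol = 1, dimnames = list(NULL, "E")))
  g <- genotype_vector(G)
  gn <- global_fit(d)
  terms <- term_spec("g-ge")
  expect_identical(terms$df, 2L)

  # oracle: scaled assembly with the two-column tested design
  mask <- as.numeric(!is.na(G))
  X1 <- cbind(1, E)
  G0 <- ifelse(is.na(G), 0, G)
  X2 <- cbind(G0, G0 * E)
  th_f <- oracle_mle(y, X1)$theta
  obm <- oracle_blocks(y, X1, X2, th_f, mask)
  obf <- oracle_blocks(y, X1, X2, th_f, rep(1, n))
  s_pm1 <- oracle_score_stat(obm$u2 / n, obf$J11, obm$J12, obm$J22, n)
  res1 <- pm1_test(gn, d, g, terms)
  expect_identical(res1$df, 2L)
  expect_equal(res1$statistic, s_pm1, tolerance = 1e-5)

  sub <- which(mask == 1)
  th_m <- oracle_mle(y[sub], X1[sub, ])$theta
  obc <- oracle_blocks(y, X1, X2, th_m, mask)
  s_cst <- oracle_score_stat(obc$u2 / n, obc$J11, obc$J12, obc$J22, n)
  expect_equal(cst_test(d, g, terms)$statistic, s_cst, tolerance = 1e-5)

  # 2-df Wald and LRT against the generic-optimizer oracle
  Xf <- cbind(1, E, G0, G0 * E)[sub, ]
  mle <- oracle_mle(y[sub], Xf)
  H <- num_hessian(function(th) oracle_loglik(y[sub], Xf, th), mle$theta)
  V <- solve(-H)[3:4, 3:4]
  w_or <- drop(t(mle$theta[3:4]) %*% solve(V) %*% mle$theta[3:4])
  expect_equal(wald_test(d, g, terms)$statistic, w_or, tolerance = 1e-4)
  l_or <- 2 * (mle$loglik - oracle_mle(y[sub], X1[sub, ])$loglik)
  expect_equal(lrt_test(d, g, terms)$statistic, l_or, tolerance = 1e-4)
})

test_that("g-ge requires a covariate and honours interaction_covar by name", {
  y <- rep(c(1, 0), 10)
  d0 <- case_control_dataset(y)
  g <- genotype_vector(rbinom(20, 2, 0.4))
  expect_error(cst_test(d0, g, term_spec("g-ge")), "covariate")

  set.seed(8)
  E <- cbind(age = rnorm(20), sex = rbinom(20, 1, 0.5))
  d <- case_control_dataset(y, E)
  gn <- fit_logistic_mle(d$y, cbind(1, E))
  r_default <- pm2_test(gn, d, g, term_spec("g-ge"))
  r_named <- pm2_test(gn, d, g, term_spec("g-ge", interaction_covar = "age"))
  r_sex <- pm2_test(gn, d, g, term_spec("g-ge", interaction_covar = "sex"))
  expect_equal(r_default$statistic, r_named$statistic)
  expect_false(isTRUE(all.equal(r_named$statistic, r_sex$statistic)))
})

test_that("run_test dispatches and enforces the global-null requirement", {
  x <- tt_fixture()
  gn <- global_fit(x$d)
  expect_equal(run_test("CST", x$d, x$g)$statistic,
               cst_test(x$d, x$g)$statistic)
  expect_equal(run_test("pm2", x$d, x$g, global_null = gn)$statistic,
               pm2_test(gn, x$d, x$g)$statistic)
  expect_error(run_test("pm1", x$d, x$g), "global null")
  expect_error(run_test("nope", x$d, x$g), "unknown method")
})
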