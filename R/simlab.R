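# Monte-Carlo laboratory: retrospective case-control sampling from a
# population logistic model, MCAR genotype masking, and rejection-rate
# (type-I error / power) estimation.
#
# Population model: a binary exposure E ~ Bernoulli(e_freq), an additively
# coded SNP G ~ Binomial(2, maf) under Hardy-Weinberg equilibrium,
# independent of E, and
#   logit Pr(Y = 1 | E, G) = b0 + log(or_e) E + log(or_g) G + log(or_ge) G E,
# with b0 solved so the population prevalence matches the target (1% by
# default). Case-control data are drawn retrospectively: sampling from
# the population until the case and control quotas are filled, which is
# distributionally identical to drawing (E, G) from their exact
# conditional distribution given Y (six cells), the fast default here.

#' Simulation configuration
#'
#' Defaults are the conditions of the reference experiments: prevalence
#' 1%, binary covariate at 50% frequency with odds ratio 1.2, SNP under
#' HWE, MCAR missingness.
#'
#' @param prevalence Population disease probability.
#' @param or_e Covariate odds ratio `exp(b_e)`.
#' @param e_freq Binary covariate population frequency.
#' @param maf Minor allele frequency.
#' @param or_g Genotype odds ratio per allele (1 under the null).
#' @param or_ge Gene-environment interaction odds ratio (1 under the null).
#' @param n_case,n_control Target counts.
#' @param missing_rate MCAR genotype missingness probability R in [0, 1).
#' @param model `"g"` (marginal test) or `"g-ge"` (joint 2-df test).
#' @param seed Optional RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(prevalence = 0.01, or_e = 1.2, e_freq = 0.5,
                              maf = 0.3, or_g = 1, or_ge = 1,
                              n_case = 1000, n_control = 1000,
                              missing_rate = 0, model = c("g", "g-ge"),
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(prevalence > 0, prevalence < 1,
            maf > 0, maf <= 0.5,
            e_freq >= 0, e_freq <= 1,
            or_e > 0, or_g > 0, or_ge > 0,
            n_case >= 1, n_control >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(prevalence = prevalence, or_e = or_e, e_freq = e_freq, maf = maf,
         or_g = or_g, or_ge = or_ge, n_case = as.integer(n_case),
         n_control = as.integer(n_control), missing_rate = missing_rate,
         model = model, seed = seed),
    class = "simulation_config"
  )
}

# Joint (E, G) population cells with case probabilities at intercept b0.
population_cells <- function(config, b0) {
  grid <- expand.grid(e = 0:1, g = 0:2)
  p_e <- ifelse(grid$e == 1, config$e_freq, 1 - config$e_freq)
  p_g <- stats::dbinom(grid$g, 2, config$maf)
  eta <- b0 + log(config$or_e) * grid$e + log(config$or_g) * grid$g +
    log(config$or_ge) * grid$g * grid$e
  data.frame(e = grid$e, g = grid$g, p = p_e * p_g,
             pi = stats::plogis(eta))
}

#' Solve the baseline intercept for a target prevalence
#'
#' Finds `b0` such that the population-averaged case probability over the
#' joint distribution of (E, G) equals `config$prevalence`, by monotone
#' root finding.
#'
#' @param config A [simulation_config()].
#' @param tol Root-finding tolerance (default `1e-10`).
#' @return The intercept `b0` (scalar).
#' @export
solve_baseline_intercept <- function(config, tol = 1e-10) {
  f <- function(b0) {
    cells <- population_cells(config, b0)
    sum(cells$p * cells$pi) - config$prevalence
  }
  stats::uniroot(f, interval = c(-40, 40), extendInt = "upX",
                 tol = tol)$root
}

#' Draw a retrospective case-control sample
#'
#' Samples `(E, G)` for exactly `n_case` cases and `n_control` controls
#' from the population model conditional on outcome. The default
#' `"conditional"` method draws cell counts from the exact distribution of
#' (E, G) given Y (a six-cell multinomial), which is distributionally
#' identical to — and far faster than — the literal `"rejection"` method
#' that simulates population individuals and keeps the first ones to fill
#' each quota.
#'
#' @param config A [simulation_config()]; `config$seed`, when set, seeds
#'   the RNG before sampling.
#' @param method `"conditional"` (exact, fast) or `"rejection"`.
#' @param max_draws Cap on population draws for `"rejection"`.
#' @return A list with `dataset` (a [case_control_dataset()] whose single
#'   covariate is `E`), `genotype` (a complete [genotype_vector()]) and
#'   `b0` (the solved intercept).
#' @export
sample_case_control <- function(config, method = c("conditional", "rejection"),
                                max_draws = 1e9) {
  method <- match.arg(method)
  if (!is.null(config$seed)) set.seed(config$seed)
  b0 <- solve_baseline_intercept(config)
  cells <- population_cells(config, b0)
  n1 <- config$n_case
  n0 <- config$n_control

  if (method == "conditional") {
    p_case <- cells$p * cells$pi
    p_ctrl <- cells$p * (1 - cells$pi)
    k1 <- drop(stats::rmultinom(1, n1, p_case / sum(p_case)))
    k0 <- drop(stats::rmultinom(1, n0, p_ctrl / sum(p_ctrl)))
    e <- c(rep(cells$e, k1), rep(cells$e, k0))
    g <- c(rep(cells$g, k1), rep(cells$g, k0))
    y <- c(rep(1, n1), rep(0, n0))
    ord <- sample.int(n1 + n0)   # shuffle so row order carries no signal
    e <- e[ord]; g <- g[ord]; y <- y[ord]
  } else {
    e <- g <- y <- numeric(0)
    got1 <- 0L; got0 <- 0L; drawn <- 0
    exp_rate <- max(sum(cells$p * cells$pi), 1e-12)
    while (got1 < n1 || got0 < n0) {
      need1 <- n1 - got1; need0 <- n0 - got0
      batch <- ceiling(max(1e4, 1.5 * max(need1 / exp_rate,
                                          need0 / (1 - exp_rate))))
      batch <- min(batch, 1e7)
      drawn <- drawn + batch
      if (drawn > max_draws) stop("draw cap exceeded before quotas filled")
      eb <- stats::rbinom(batch, 1, config$e_freq)
      gb <- stats::rbinom(batch, 2, config$maf)
      eta <- b0 + log(config$or_e) * eb + log(config$or_g) * gb +
        log(config$or_ge) * gb * eb
      yb <- stats::rbinom(batch, 1, stats::plogis(eta))
      take1 <- which(yb == 1)[seq_len(min(need1, sum(yb == 1)))]
      take0 <- which(yb == 0)[seq_len(min(need0, sum(yb == 0)))]
      take <- sort(c(take1, take0))
      e <- c(e, eb[take]); g <- c(g, gb[take]); y <- c(y, yb[take])
      got1 <- sum(y == 1); got0 <- sum(y == 0)
    }
  }

  list(
    dataset = case_control_dataset(y, E = matrix(e, ncol = 1,
                                                 dimnames = list(NULL, "E"))),
    genotype = genotype_vector(g),
    b0 = b0
  )
}

#' Mask genotypes missing-completely-at-random
#'
#' Each entry is independently set to missing with probability `R`,
#' independent of outcome, covariates and genotype value.
#'
#' @param g A [genotype_vector()].
#' @param R Missingness probability in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return A [genotype_vector()] with the MCAR mask applied.
#' @export
apply_mcar <- function(g, R, seed = NULL) {
  stopifnot(R >= 0, R < 1)
  if (!is.null(seed)) set.seed(seed)
  codes <- g$codes
  if (R > 0) codes[stats::runif(length(codes)) < R] <- NA
  genotype_vector(codes, marker = g$marker)
}

#' Monte-Carlo standard error and interval for a rejection rate
#'
#' The binomial standard error `sqrt(a (1 - a) / n_reps)` of an estimated
#' rejection rate at nominal level `a`, and the normal-approximation
#' interval `a +/- z * se` used to judge whether an estimate is consistent
#' with the nominal level.
#'
#' @param alpha Nominal level.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param level Interval coverage (default 0.95).
#' @return List with `se`, `lower`, `upper`.
#' @export
rejection_interval <- function(alpha, n_reps, level = 0.95) {
  se <- sqrt(alpha * (1 - alpha) / n_reps)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(se = se, lower = alpha - z * se, upper = alpha + z * se)
}

# Deterministic per-replicate seed below 2^31, derived from (seed, index).
replicate_seed <- function(seed, j) {
  (as.double(seed) * 48271 + as.double(j) * 16807) %% 2147483647
}

# --- fast Monte-Carlo engine -----------------------------------------------
# The public test functions build validated containers per call; at 10^4-10^6
# replicates that overhead dominates, so the harness uses this lean path on
# raw vectors. It shares the null fit and the missing-weighted blocks across
# CST/PM1/PM2/median within a replicate. A unit test pins it to the public
# run_test() path replicate-by-replicate.

# Case-control draw from precomputed conditional cells; returns raw vectors.
cc_draw <- function(cells, n1, n0) {
  p_case <- cells$p * cells$pi
  p_ctrl <- cells$p * (1 - cells$pi)
  k1 <- drop(stats::rmultinom(1, n1, p_case / sum(p_case)))
  k0 <- drop(stats::rmultinom(1, n0, p_ctrl / sum(p_ctrl)))
  e <- c(rep.int(cells$e, k1), rep.int(cells$e, k0))
  g <- c(rep.int(cells$g, k1), rep.int(cells$g, k0))
  y <- c(rep.int(1, n1), rep.int(0, n0))
  ord <- sample.int(n1 + n0)
  list(y = y[ord], e = e[ord], g = g[ord])
}

# Newton-Raphson on raw matrices, no containers; mirrors fit_logistic_mle
# (same init, tolerance, iteration cap, step-halving) minus bookkeeping.
newton_theta <- function(y, X, tol = 1e-8, max_iter = 50L) {
  theta <- numeric(ncol(X))
  ll <- log_likelihood(y, X, theta)
  for (iter in seq_len(max_iter)) {
    p <- clamp_prob(stats::plogis(drop(X %*% theta)))
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X, X * (p * (1 - p)))
    if (max(abs(score)) <= tol) {
      polish <- tryCatch(solve(info, score), error = function(e) NULL)
      if (!is.null(polish) &&
          log_likelihood(y, X, theta + polish) >= ll - 1e-10) {
        theta <- theta + polish
      }
      return(theta)
    }
    step <- solve(info, score)
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_cand <- log_likelihood(y, X, cand)
      if (ll_cand >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- cand
    ll <- ll_cand
  }
  theta
}

# All requested p-values (and statistics) for one replicate.
# codes: genotype with NA for missing; model: "g" or "g-ge".
replicate_pvalues <- function(y, e, codes, model, methods) {
  out_p <- stats::setNames(rep(NA_real_, length(methods)), methods)
  out_s <- out_p
  obs <- codes[!is.na(codes)]
  if (length(unique(obs)) < 2L) {
    return(list(p = out_p, stat = out_s))
  }
  n <- length(y)
  mask <- as.numeric(!is.na(codes))
  codes0 <- ifelse(is.na(codes), 0, codes)
  X1 <- cbind(1, e)
  X2 <- if (model == "g") matrix(codes0, ncol = 1) else
    cbind(codes0, codes0 * e)
  df <- ncol(X2)

  stat_of <- function(U, C) {
    v <- quad_form(U, C)
    if (is.null(v)) NA_real_ else v
  }
  record <- function(m, stat) {
    out_s[[m]] <<- stat
    out_p[[m]] <<- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }

  if (any(methods %in% c("pm1", "pm2", "median"))) {
    th_f <- newton_theta(y, X1)
    rbm <- raw_blocks(y, X1, X2, th_f, mask)
    if ("pm1" %in% methods) {
      S11f <- crossprod(X1, X1 * rbm$weights)
      record("pm1", stat_of(rbm$u2, schur_complement(rbm$S22, rbm$S12, S11f)))
    }
    if ("pm2" %in% methods) {
      Bt <- tryCatch(solve(rbm$S11, rbm$S12), error = function(err) NULL)
      if (!is.null(Bt)) {
        Ustar <- rbm$u2 - drop(crossprod(Bt, rbm$u1))
        record("pm2", stat_of(Ustar, rbm$S22 - crossprod(rbm$S12, Bt)))
      }
    }
    if ("median" %in% methods) {
      med <- stats::median(obs)
      fill <- floor(med + 0.5 - .Machine$double.eps^0.5)
      ci <- ifelse(is.na(codes), fill, codes)
      X2i <- if (model == "g") matrix(ci, ncol = 1) else cbind(ci, ci * e)
      rbi <- raw_blocks(y, X1, X2i, th_f, rep(1, n))
      record("median",
             stat_of(rbi$u2, schur_complement(rbi$S22, rbi$S12, rbi$S11)))
    }
  }
  sub <- NULL
  if (any(methods %in% c("cst", "wald", "lrt"))) {
    sub <- which(mask == 1)
    ys <- y[sub]
    if (all(ys == ys[1])) return(list(p = out_p, stat = out_s))
  }
  if ("cst" %in% methods) {
    th_m <- newton_theta(y[sub], X1[sub, , drop = FALSE])
    rbc <- raw_blocks(y, X1, X2, th_m, mask)
    record("cst", stat_of(rbc$u2, schur_complement(rbc$S22, rbc$S12, rbc$S11)))
  }
  if (any(methods %in% c("wald", "lrt"))) {
    Xf <- cbind(X1, X2)[sub, , drop = FALSE]
    th_full <- newton_theta(y[sub], Xf)
    if ("wald" %in% methods) {
      p <- clamp_prob(stats::plogis(drop(Xf %*% th_full)))
      info <- crossprod(Xf, Xf * (p * (1 - p)))
      V <- tryCatch(solve(info), error = function(err) NULL)
      if (!is.null(V)) {
        idx2 <- ncol(X1) + seq_len(df)
        record("wald", stat_of(th_full[idx2], V[idx2, idx2, drop = FALSE]))
      }
    }
    if ("lrt" %in% methods) {
      th0 <- newton_theta(y[sub], X1[sub, , drop = FALSE])
      record("lrt", max(0, 2 * (log_likelihood(y[sub], Xf, th_full) -
                                  log_likelihood(y[sub],
                                                 X1[sub, , drop = FALSE],
                                                 th0))))
    }
  }
  list(p = out_p, stat = out_s)
}

#' Estimate rejection rates by Monte-Carlo simulation
#'
#' For each replicate: draw a retrospective case-control sample, apply
#' MCAR masking, run every requested test on the same replicate (paired
#' design), and compare p-values with each nominal level. Replicates where
#' a test does not return status `"ok"` are excluded from that test's
#' denominator and counted.
#'
#' @param config A [simulation_config()]; `config$seed` drives one
#'   independent RNG stream per replicate.
#' @param n_reps Number of replicates.
#' @param alpha Nominal level(s); may be a vector, evaluated on the same
#'   replicates.
#' @param methods Character vector of method tags (see [run_test()]).
#' @param keep_stats Attach the replicate x method matrix of statistics
#'   (and p-values) as attributes `statistics` / `p_values`?
#' @return A data frame of class `rejection_estimates`: one row per
#'   method x alpha with columns `method`, `alpha`, `n_reps`, `n_ok`,
#'   `rejections`, `rate`, `se` (binomial SE at the nominal level),
#'   `ci_low`/`ci_high` (95% normal interval around the nominal level) and
#'   `ci_exact_low`/`ci_exact_high` (exact binomial 95% interval around
#'   the estimate).
#' @export
estimate_rejection <- function(config, n_reps, alpha = 0.05,
                               methods = c("cst", "pm1", "pm2"),
                               keep_stats = FALSE) {
  stopifnot(n_reps >= 1, all(alpha > 0), all(alpha < 1))
  methods <- tolower(methods)
  seed0 <- if (is.null(config$seed)) 1L else config$seed

  pvals <- matrix(NA_real_, nrow = n_reps, ncol = length(methods),
                  dimnames = list(NULL, methods))
  stats_m <- if (keep_stats) pvals else NULL

  b0 <- solve_baseline_intercept(config)
  cells <- population_cells(config, b0)
  R <- config$missing_rate
  for (j in seq_len(n_reps)) {
    set.seed(replicate_seed(seed0, j))
    d <- cc_draw(cells, config$n_case, config$n_control)
    codes <- d$g
    if (R > 0) codes[stats::runif(length(codes)) < R] <- NA
    rep_res <- replicate_pvalues(d$y, d$e, codes, config$model, methods)
    pvals[j, ] <- rep_res$p[methods]
    if (keep_stats) stats_m[j, ] <- rep_res$stat[methods]
  }

  out <- do.call(rbind, lapply(methods, function(m) {
    pm <- pvals[, m]
    n_ok <- sum(!is.na(pm))
    do.call(rbind, lapply(alpha, function(a) {
      rej <- sum(pm <= a, na.rm = TRUE)
      iv <- rejection_interval(a, n_ok)
      ex <- if (n_ok > 0) stats::binom.test(rej, n_ok)$conf.int else c(NA, NA)
      data.frame(method = m, alpha = a, n_reps = n_reps, n_ok = n_ok,
                 rejections = rej, rate = if (n_ok > 0) rej / n_ok else NA,
                 se = iv$se, ci_low = iv$lower, ci_high = iv$upper,
                 ci_exact_low = ex[1], ci_exact_high = ex[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  if (keep_stats) {
    attr(out, "statistics") <- stats_m
    attr(out, "p_values") <- pvals
  }
  class(out) <- c("rejection_estimates", class(out))
  out
}

#' Null test statistics across many independent SNPs
#'
#' Draws one case-control sample of (Y, E), then simulates `n_snps`
#' independent SNPs (HWE at `config$maf`, independent of the phenotype, as
#' under the global null), applies MCAR masking per SNP and returns the
#' statistic of each requested test. Mirrors a null genome scan and feeds
#' Q-Q and test-concordance diagnostics.
#'
#' @param config A [simulation_config()] (its `or_g`/`or_ge` are ignored:
#'   SNPs are drawn under the null).
#' @param n_snps Number of SNPs.
#' @param methods Method tags.
#' @return `n_snps x length(methods)` matrix of statistics (NA where a
#'   test did not return `"ok"`).
#' @export
null_snp_statistics <- function(config, n_snps,
                                methods = c("cst", "pm2")) {
  methods <- tolower(methods)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_null <- config
  cfg_null$or_g <- 1
  cfg_null$or_ge <- 1
  b0 <- solve_baseline_intercept(cfg_null)
  cells <- population_cells(cfg_null, b0)
  d <- cc_draw(cells, config$n_case, config$n_control)
  n <- length(d$y)
  R <- config$missing_rate

  out <- matrix(NA_real_, nrow = n_snps, ncol = length(methods),
                dimnames = list(NULL, methods))
  for (s in seq_len(n_snps)) {
    codes <- stats::rbinom(n, 2, config$maf)
    if (R > 0) codes[stats::runif(n) < R] <- NA
    out[s, ] <- replicate_pvalues(d$y, d$e, codes, config$model,
                                  methods)$stat[methods]
  }
  out
}

#' Top-quantile pairs for a chi-squared Q-Q plot
#'
#' Pairs the largest `top_k` observed statistics (ascending) with the
#' chi-squared quantiles at the matching plotting positions
#' `(i - 0.5) / n`.
#'
#' @param statistics Non-negative statistic vector.
#' @param df Chi-squared degrees of freedom (>= 1).
#' @param top_k Number of top order statistics to keep.
#' @return Data frame with non-decreasing columns `theoretical`,
#'   `observed`, `top_k` rows.
#' @export
qq_statistics <- function(statistics, df, top_k) {
  if (df < 1) stop("df must be >= 1")
  statistics <- statistics[!is.na(statistics)]
  n <- length(statistics)
  stopifnot(top_k >= 1, top_k <= n, all(statistics >= 0))
  obs <- sort(statistics)[(n - top_k + 1):n]
  ranks <- (n - top_k + 1):n
  theo <- stats::qchisq((ranks - 0.5) / n, df = df)
  data.frame(theoretical = theo, observed = obs)
}

#' Command-line simulation harness
#'
#' Backs the `simulate` CLI script in `inst/cli/`. First positional
#' argument is `type1` (forces the null) or `power`; writes a CSV with one
#' row per method x alpha.
#'
#' @param argv Character vector of command-line arguments.
#' @return Invisibly, the `rejection_estimates` data frame.
#' @export
simulate_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    prog = "simulate",
    usage = "simulate type1|power [options]",
    description = "Monte-Carlo type-I-error / power experiments")
  parser <- optparse::add_option(parser, "--model", type = "character",
                                 default = "g", help = "g or g-ge")
  parser <- optparse::add_option(parser, "--maf", type = "double",
                                 default = 0.3)
  parser <- optparse::add_option(parser, "--missing", type = "double",
                                 default = 0.05)
  parser <- optparse::add_option(parser, "--n-case", type = "integer",
                                 dest = "n_case", default = 1000L)
  parser <- optparse::add_option(parser, "--n-control", type = "integer",
                                 dest = "n_control", default = 1000L)
  parser <- optparse::add_option(parser, "--or-g", type = "double",
                                 dest = "or_g", default = 1)
  parser <- optparse::add_option(parser, "--or-ge", type = "double",
                                 dest = "or_ge", default = 1)
  parser <- optparse::add_option(parser, "--alpha", type = "character",
                                 default = "0.05",
                                 help = "comma-separated nominal levels")
  parser <- optparse::add_option(parser, "--reps", type = "integer",
                                 default = 1000L)
  parser <- optparse::add_option(parser, "--methods", type = "character",
                                 default = "cst,pm1,pm2")
  parser <- optparse::add_option(parser, "--seed", type = "integer",
                                 default = 1L)
  parser <- optparse::add_option(parser, "--out", type = "character",
                                 help = "output CSV path")
  args <- optparse::parse_args(parser, args = argv, positional_arguments = 1)
  mode <- args$args[1]
  opt <- args$options
  if (!mode %in% c("type1", "power")) stop("mode must be type1 or power")
  if (mode == "type1") {
    opt$or_g <- 1
    opt$or_ge <- 1
  }
  cfg <- simulation_config(
    maf = opt$maf, or_g = opt$or_g, or_ge = opt$or_ge,
    n_case = opt$n_case, n_control = opt$n_control,
    missing_rate = opt$missing, model = opt$model, seed = opt$seed)
  alphas <- as.numeric(strsplit(opt$alpha, ",")[[1]])
  methods <- strsplit(opt$methods, ",")[[1]]
  est <- estimate_rejection(cfg, n_reps = opt$reps, alpha = alphas,
                            methods = methods)
  if (!is.null(opt$out)) {
    utils::write.csv(est, opt$out, row.names = FALSE)
  } else {
    print(est)
  }
  invisible(est)
}
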