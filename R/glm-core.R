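# Logistic-regression likelihood, score and information-block algebra.
#
# Everything downstream (the six association tests and the genome scan)
# reduces to sums of per-individual score contributions
#   u1i = X1i (y_i - pi_i),  u2i = X2i (y_i - pi_i)
# and weighted cross-product blocks
#   J[j,k] = (1/n) sum w_i Xji Xki',  w_i = pi_i (1 - pi_i),
# optionally multiplied by the genotype observation indicator I_i
# ("missing-weighted"). For the canonical logit link the observed and
# expected information coincide, so the J blocks double as the negative
# scaled Hessian of the log-likelihood.

.globalscore_env <- new.env(parent = emptyenv())
.globalscore_env$fit_count <- 0L

#' Reset the maximum-likelihood fit counter
#'
#' Every call to [fit_logistic_mle()] increments a package-level counter.
#' The genome scan resets it before running so callers (and tests) can
#' verify the structural contract that a PM1/PM2 scan performs exactly one
#' null fit no matter how many markers are tested.
#' @return Invisibly, the previous counter value.
#' @export
reset_fit_counter <- function() {
  old <- .globalscore_env$fit_count
  .globalscore_env$fit_count <- 0L
  invisible(old)
}

#' Read the maximum-likelihood fit counter
#' @return Integer number of Newton-Raphson fits since the last reset.
#' @export
fit_counter <- function() .globalscore_env$fit_count

# Clamp fitted probabilities away from 0/1 so the log-likelihood is always
# finite; 1e-12 is far below any tolerance used by the tests.
.PI_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, .PI_EPS), 1 - .PI_EPS)

#' Bernoulli log-likelihood of a logistic model
#'
#' @param y Binary outcome vector.
#' @param X Design matrix (including the intercept column).
#' @param theta Coefficient vector.
#' @return The log-likelihood, a finite scalar (probabilities are clamped
#'   to `[1e-12, 1 - 1e-12]` so rounding can never produce `-Inf`).
#' @export
log_likelihood <- function(y, X, theta) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(theta) == ncol(X))
  p <- clamp_prob(stats::plogis(drop(X %*% theta)))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a logistic regression by Newton-Raphson
#'
#' Plain maximum likelihood with the canonical link. Convergence is
#' declared when the infinity norm of the score vector drops below `tol`;
#' step-halving guards against overshooting near-separated data. Diverging
#' coefficients (quasi-complete separation) are flagged, never returned
#' silently as converged.
#'
#' @param y Binary outcome vector.
#' @param X Design matrix with an intercept column.
#' @param subset Optional integer index vector of rows used in the fit
#'   (e.g. the complete-case subset of a SNP); defaults to all rows.
#' @param tol Convergence tolerance on `max |score|` (default `1e-8`).
#' @param max_iter Iteration cap (default 50).
#' @return An object of class `logistic_fit`: `theta`, `pi`, `resid`,
#'   `weights` (aligned with `subset`), `vcov` (inverse information on the
#'   fitted subset), `loglik`, `converged`, `separation`, `n_iter`,
#'   `subset`.
#' @export
fit_logistic_mle <- function(y, X, subset = NULL, tol = 1e-8,
                             max_iter = 50L) {
  X <- as.matrix(X)
  if (is.null(subset)) subset <- seq_along(y)
  if (length(subset) == 0L) stop("empty subset")
  .globalscore_env$fit_count <- .globalscore_env$fit_count + 1L

  ys <- y[subset]
  Xs <- X[subset, , drop = FALSE]
  if (all(ys == ys[1])) stop("outcome has a single class on the fitted subset")

  p <- ncol(Xs)
  theta <- numeric(p)
  ll <- log_likelihood(ys, Xs, theta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  info <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    pi_s <- clamp_prob(stats::plogis(drop(Xs %*% theta)))
    w <- pi_s * (1 - pi_s)
    score <- drop(crossprod(Xs, ys - pi_s))
    info <- crossprod(Xs, Xs * w)
    if (max(abs(score)) <= tol) {
      converged <- TRUE
      # one polishing step: quadratic convergence takes the score norm from
      # the 1e-8 tolerance to machine precision, so downstream identities
      # that assume an exact null score (e.g. the no-missing equality of
      # the three score tests) hold to ~1e-12 rather than ~1e-8
      polish <- tryCatch(solve(info, score), error = function(e) NULL)
      if (!is.null(polish)) {
        cand <- theta + polish
        ll_cand <- log_likelihood(ys, Xs, cand)
        if (ll_cand >= ll - 1e-10) {
          theta <- cand
          ll <- ll_cand
        }
      }
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      break
    }
    # step-halving: accept the first step that does not decrease loglik
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_cand <- log_likelihood(ys, Xs, cand)
      if (ll_cand >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- cand
    ll <- ll_cand
    if (max(abs(theta)) > 1e2) {
      separation <- TRUE
      break
    }
  }
  # refresh fitted quantities at the final coefficients (the loop's cached
  # values predate the polishing step / last update)
  pi_s <- clamp_prob(stats::plogis(drop(Xs %*% theta)))
  w <- pi_s * (1 - pi_s)
  info <- crossprod(Xs, Xs * w)
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  # a "converged" fit with huge coefficients is quasi-complete separation:
  # the score vanishes as fitted probabilities saturate, so the score-norm
  # criterion alone cannot distinguish it from a genuine interior MLE
  if (max(abs(theta)) > 20) separation <- TRUE

  structure(
    list(theta = stats::setNames(drop(theta), colnames(Xs)),
         pi = pi_s, resid = ys - pi_s, weights = pi_s * (1 - pi_s),
         vcov = vcov, loglik = ll, converged = converged,
         separation = separation, n_iter = iter, subset = subset),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit on %d rows: loglik = %.6g, %s in %d iteration(s)\n",
              length(x$subset), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$theta)
  invisible(x)
}

# Raw (unnormalized) score sums and information blocks at a null value of
# theta1, evaluated over all n individuals, with every term multiplied by
# the weight vector `iw` (the observation mask for the missing-weighted
# blocks, all ones for the full-sample blocks). Returns sums; callers
# divide by n when the (1/n)-scaled blocks are wanted. The 1/n factors
# cancel inside every quadratic-form statistic, so the tests use these raw
# sums directly.
raw_blocks <- function(y, X1, X2, theta1, iw) {
  pi_ <- clamp_prob(stats::plogis(drop(X1 %*% theta1)))
  r <- y - pi_
  w <- pi_ * (1 - pi_)
  wi <- w * iw
  U1i <- X1 * (r * iw)          # n x p1 per-individual contributions
  U2i <- X2 * (r * iw)          # n x p2
  list(
    u1 = colSums(U1i),
    u2 = colSums(U2i),
    S11 = crossprod(X1, X1 * wi),
    S12 = crossprod(X1, X2 * wi),
    S22 = crossprod(X2, X2 * wi),
    per_u1 = U1i, per_u2 = U2i,
    resid = r, weights = w
  )
}

#' Score vectors and information blocks at a null fit
#'
#' Evaluates the per-individual score contributions and the four
#' information blocks at the null-model coefficients stored in `fit`,
#' over all individuals in the dataset. With `missing_weighted = TRUE`
#' (the default) every contribution is multiplied by the genotype
#' observation indicator, so individuals with a missing genotype
#' contribute exactly zero; this yields the superscript-m blocks of the
#' complete-case score algebra. J blocks carry the -(1/n) d u / d theta
#' scaling.
#'
#' @param fit A `logistic_fit` for the null model (genotype terms absent).
#' @param dataset A [case_control_dataset()].
#' @param g A [genotype_vector()].
#' @param terms A [term_spec()].
#' @param missing_weighted Multiply contributions by the observation mask?
#' @return Object of class `score_blocks`: `u1`, `u2`, `J11_11`, `J11_12`,
#'   `J11_21`, `J11_22`, `per_individual_u1`, `per_individual_u2`,
#'   `missing_weighted`, `n`.
#' @export
score_blocks <- function(fit, dataset, g, terms = term_spec("g"),
                         missing_weighted = TRUE) {
  if (g$n_obs == 0L) stop("all genotypes are missing")
  X1 <- build_x1(dataset)
  X2 <- build_x2(dataset, g, terms)
  n <- dataset$n
  iw <- if (missing_weighted) g$mask else rep(1, n)
  rb <- raw_blocks(dataset$y, X1, X2, fit$theta, iw)
  structure(
    list(u1 = rb$u1, u2 = rb$u2,
         J11_11 = rb$S11 / n, J11_12 = rb$S12 / n,
         J11_21 = t(rb$S12) / n, J11_22 = rb$S22 / n,
         per_individual_u1 = rb$per_u1, per_individual_u2 = rb$per_u2,
         missing_weighted = missing_weighted, n = n),
    class = "score_blocks"
  )
}
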