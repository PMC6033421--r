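#' Case-control dataset
#'
#' Bundles the binary outcome and the complete covariate matrix that the
#' null model sees. Covariates must be fully observed: the whole point of
#' the global-null machinery is that only genotypes can be missing, so rows
#' with missing outcome or covariates are rejected here rather than being
#' silently dropped downstream.
#'
#' @param y Binary outcome vector (1 = case, 0 = control).
#' @param E Optional numeric covariate matrix (or vector) with one row per
#'   individual; may be `NULL` for an intercept-only null model.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to `"S1", "S2", ...`.
#'
#' @return An object of class `case_control_dataset` with elements `y`,
#'   `E` (an `n x p_e` matrix, possibly zero-column), `sample_ids` and `n`.
#' @export
case_control_dataset <- function(y, E = NULL, sample_ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) stop("empty outcome vector")
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be coded 0/1 with no missing values")
  }
  if (sum(y) == 0 || sum(y) == n) {
    stop("need at least one case and one control")
  }
  if (is.null(E)) {
    E <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    E <- as.matrix(E)
    if (!is.numeric(E)) stop("covariates must be numeric")
    if (nrow(E) != n) stop("covariate rows must align with the outcome")
    if (anyNA(E)) stop("covariates must not contain missing values")
    if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids must have one entry per row")
  structure(
    list(y = y, E = E, sample_ids = sample_ids, n = n),
    class = "case_control_dataset"
  )
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat(sprintf(
    "case_control_dataset: %d individuals (%d cases / %d controls), %d covariate(s)\n",
    x$n, sum(x$y == 1), sum(x$y == 0), ncol(x$E)
  ))
  invisible(x)
}

#' Per-SNP genotype vector with missing mask
#'
#' Additive genotype codes (count of the effect allele, 0/1/2) with `NA`
#' marking missing calls. The observation indicator `mask` (1 = observed)
#' is what the missing-weighted score algebra multiplies into every
#' genotype-bearing term, so missing codes never enter arithmetic.
#'
#' @param codes Numeric vector over `{0, 1, 2, NA}`.
#' @param marker Optional list with elements `id`, `chromosome`,
#'   `position`, `allele_A1`, `allele_A2`.
#'
#' @return Object of class `genotype_vector` with `codes`, `mask`,
#'   `marker`, `n_obs`, `maf_obs`.
#' @export
genotype_vector <- function(codes, marker = NULL) {
  codes <- as.numeric(codes)
  obs <- codes[!is.na(codes)]
  if (length(obs) && !all(obs %in% c(0, 1, 2))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  mask <- as.numeric(!is.na(codes))
  n_obs <- as.integer(sum(mask))
  maf_obs <- if (n_obs > 0L) {
    p <- mean(obs) / 2
    min(p, 1 - p)
  } else {
    NA_real_
  }
  if (is.null(marker)) {
    marker <- list(id = "SNP", chromosome = "0", position = 0L,
                   allele_A1 = "A", allele_A2 = "B")
  }
  structure(
    list(codes = codes, mask = mask, marker = marker,
         n_obs = n_obs, maf_obs = maf_obs),
    class = "genotype_vector"
  )
}

#' @export
print.genotype_vector <- function(x, ...) {
  cat(sprintf(
    "genotype_vector %s: n = %d, observed = %d, observed MAF = %s\n",
    x$marker$id, length(x$codes), x$n_obs,
    ifelse(is.na(x$maf_obs), "NA", format(x$maf_obs, digits = 4))
  ))
  invisible(x)
}

#' Specify which genotype-derived terms are tested
#'
#' `"g"` tests the 1-df marginal genotype effect; `"g-ge"` tests the joint
#' 2-df hypothesis that both the genotype main effect and the
#' genotype-by-environment interaction are zero. The interacting covariate
#' defaults to the first covariate column and can be selected by name.
#'
#' @param kind `"g"` or `"g-ge"`.
#' @param interaction_covar Covariate name (or column index) used for the
#'   interaction term under `"g-ge"`; ignored for `"g"`.
#'
#' @return Object of class `term_spec` with `kind`, `df`,
#'   `interaction_covar`.
#' @export
term_spec <- function(kind = c("g", "g-ge"), interaction_covar = NULL) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, df = if (kind == "g") 1L else 2L,
         interaction_covar = interaction_covar),
    class = "term_spec"
  )
}

# Build the tested-term design X2 (n x df) from a genotype vector with
# missing codes zeroed; the observation mask zeroes the same rows in every
# weighted sum so the placeholder never influences a statistic.
build_x2 <- function(dataset, g, terms) {
  codes0 <- ifelse(is.na(g$codes), 0, g$codes)
  if (terms$kind == "g") {
    X2 <- matrix(codes0, ncol = 1)
    colnames(X2) <- "G"
  } else {
    if (ncol(dataset$E) < 1L) {
      stop("joint gene-environment test requires at least one covariate")
    }
    ic <- terms$interaction_covar
    if (is.null(ic)) ic <- 1L
    if (is.character(ic)) {
      idx <- match(ic, colnames(dataset$E))
      if (is.na(idx)) stop("interaction covariate not found: ", ic)
      ic <- idx
    }
    Ei <- dataset$E[, ic]
    X2 <- cbind(G = codes0, GxE = codes0 * Ei)
  }
  X2
}

# Null-model design (intercept + covariates).
build_x1 <- function(dataset) {
  X1 <- cbind(`(Intercept)` = rep(1, dataset$n), dataset$E)
  X1
}

#' Association test result
#'
#' @param method Method tag (`"CST"`, `"PM1"`, `"PM2"`, `"WALD"`, `"LRT"`,
#'   `"MEDIAN_IMPUTE"`).
#' @param statistic Chi-squared statistic (NA unless `status == "ok"`).
#' @param df Degrees of freedom.
#' @param n_total,n_observed Total individuals and individuals with an
#'   observed genotype.
#' @param status One of `"ok"`, `"monomorphic"`, `"not_converged"`,
#'   `"degenerate_variance"`.
#' @return Object of class `assoc_test_result`.
#' @keywords internal
test_result <- function(method, statistic, df, n_total, n_observed,
                        status = "ok") {
  p_value <- if (identical(status, "ok")) {
    stats::pchisq(statistic, df = df, lower.tail = FALSE)
  } else {
    NA_real_
  }
  structure(
    list(method = method, statistic = statistic, df = as.integer(df),
         p_value = p_value, n_total = as.integer(n_total),
         n_observed = as.integer(n_observed), status = status),
    class = "assoc_test_result"
  )
}

#' @export
print.assoc_test_result <- function(x, ...) {
  if (identical(x$status, "ok")) {
    cat(sprintf("%s: chi-sq(%d) = %.6g, p = %.4e (n = %d, observed = %d)\n",
                x$method, x$df, x$statistic, x$p_value, x$n_total,
                x$n_observed))
  } else {
    cat(sprintf("%s: status = %s (n = %d, observed = %d)\n",
                x$method, x$status, x$n_total, x$n_observed))
  }
  invisible(x)
}
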