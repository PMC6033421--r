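# Genome-wide scan: one global null fit, per-marker test dispatch,
# PLINK-like tab-separated output.

#' Genome-wide association scan
#'
#' Runs the requested tests on every marker of a study. Individuals with a
#' missing phenotype (or any missing covariate) are excluded once, up
#' front, before the global null fit. For the single-fit methods
#' (`pm1`, `pm2`, `median`) exactly one null maximum-likelihood fit is
#' performed for the whole scan, regardless of marker count or
#' missingness pattern — the structural property that makes these tests
#' fast. Per-marker failures are recorded in the `STATUS` column and never
#' abort the scan.
#'
#' @param study A `genotype_study` from [read_plink()].
#' @param methods Character vector of method tags among
#'   `"cst"`, `"pm1"`, `"pm2"`, `"wald"`, `"lrt"`, `"median"`.
#' @param terms A [term_spec()].
#' @param covariates Optional numeric matrix of covariates aligned with
#'   the study's `.fam` rows (before exclusions).
#' @param phenotype Optional 0/1 vector overriding the `.fam` phenotype.
#' @param coding `"a1"` (default) counts the A1 allele, `"a2"` counts A2
#'   (codes flipped as 2 - G).
#' @return A data frame of class `scan_result`, one row per marker x
#'   method, with columns CHR, SNP, BP, A1, TEST, NMISS, STAT, DF, P,
#'   STATUS, and attributes `n_used`, `n_excluded`, `null_fits` (value of
#'   the fit counter consumed by the scan).
#' @export
gwas_scan <- function(study, methods = c("pm1", "pm2"),
                      terms = term_spec("g"), covariates = NULL,
                      phenotype = NULL, coding = c("a1", "a2")) {
  coding <- match.arg(coding)
  methods <- tolower(methods)
  bad <- setdiff(methods, c("cst", "pm1", "pm2", "wald", "lrt", "median"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))

  y_all <- if (is.null(phenotype)) study$fam$y else phenotype
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == study$n)
  }
  keep <- !is.na(y_all)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  keep_idx <- which(keep)
  if (length(keep_idx) == 0L) stop("no analyzable individuals after exclusions")

  dataset <- case_control_dataset(
    y = y_all[keep_idx],
    E = if (is.null(covariates)) NULL else covariates[keep_idx, , drop = FALSE],
    sample_ids = study$fam$IID[keep_idx])

  reset_fit_counter()
  global_null <- NULL
  if (any(methods %in% c("pm1", "pm2", "median"))) {
    global_null <- fit_logistic_mle(dataset$y, build_x1(dataset))
  }

  rows <- vector("list", study$marker_count * length(methods))
  k <- 0L
  for (j in seq_len(study$marker_count)) {
    gj <- study_genotype(study, j)
    codes <- gj$codes[keep_idx]
    if (coding == "a2") codes <- 2 - codes
    res_g <- tryCatch(genotype_vector(codes, marker = gj$marker),
                      error = function(e) NULL)
    for (m in methods) {
      k <- k + 1L
      res <- if (is.null(res_g)) {
        test_result(toupper(m), NA_real_, terms$df, dataset$n, 0L, "error")
      } else {
        tryCatch(run_test(m, dataset, res_g, terms, global_null),
                 error = function(e) test_result(
                   toupper(m), NA_real_, terms$df, dataset$n,
                   res_g$n_obs, "error"))
      }
      rows[[k]] <- data.frame(
        CHR = gj$marker$chromosome, SNP = gj$marker$id,
        BP = gj$marker$position, A1 = gj$marker$allele_A1,
        TEST = res$method, NMISS = res$n_observed,
        STAT = res$statistic, DF = res$df, P = res$p_value,
        STATUS = res$status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- dataset$n
  attr(out, "n_excluded") <- study$n - dataset$n
  attr(out, "null_fits") <- fit_counter()
  class(out) <- c("scan_result", class(out))
  out
}

#' Write scan results as a PLINK-like table
#'
#' Tab-separated with header `CHR SNP BP A1 TEST NMISS STAT DF P`;
#' p-values in scientific notation with 4 significant digits; statistics
#' and p-values of failed rows are `NA`.
#'
#' @param rows A `scan_result` (or compatible data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(rows, path) {
  if (nrow(rows) == 0L) stop("no rows to write")
  fmt <- data.frame(
    CHR = rows$CHR, SNP = rows$SNP, BP = rows$BP, A1 = rows$A1,
    TEST = rows$TEST, NMISS = rows$NMISS,
    STAT = ifelse(is.na(rows$STAT), "NA", sprintf("%.6g", rows$STAT)),
    DF = rows$DF,
    P = ifelse(is.na(rows$P), "NA", sprintf("%.4e", rows$P)),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Command-line genome scan
#'
#' Backs the `scan` CLI script in `inst/cli/`. Arguments mirror PLINK
#' conventions; see the package README. Returns (invisibly) the scan
#' result after writing `--out`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Invisibly, the `scan_result`.
#' @export
scan_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    prog = "scan",
    description = "Genome-wide logistic-regression score-test scan")
  parser <- optparse::add_option(parser, "--bfile", type = "character",
                                 help = "PLINK binary fileset prefix")
  parser <- optparse::add_option(parser, "--pheno", type = "character",
                                 help = "alternate phenotype file")
  parser <- optparse::add_option(parser, "--pheno-name", type = "character",
                                 dest = "pheno_name",
                                 help = "phenotype column name")
  parser <- optparse::add_option(parser, "--covar", type = "character",
                                 help = "covariate file")
  parser <- optparse::add_option(parser, "--covar-names", type = "character",
                                 dest = "covar_names",
                                 help = "comma-separated covariate columns")
  parser <- optparse::add_option(parser, "--method", type = "character",
                                 default = "pm2",
                                 help = "comma-separated: cst,pm1,pm2,wald,lrt,median")
  parser <- optparse::add_option(parser, "--test", type = "character",
                                 default = "g", help = "g or g-ge")
  parser <- optparse::add_option(parser, "--interaction-covar",
                                 type = "character", dest = "interaction_covar",
                                 help = "covariate used in the G x E term")
  parser <- optparse::add_option(parser, "--coding", type = "character",
                                 default = "a1", help = "a1 or a2 allele counts")
  parser <- optparse::add_option(parser, "--out", type = "character",
                                 help = "output table path")
  parser <- optparse::add_option(parser, "--seed", type = "integer",
                                 default = NULL, help = "RNG seed (unused by the scan itself)")
  opt <- optparse::parse_args(parser, args = argv)
  if (is.null(opt$bfile) || is.null(opt$out)) {
    stop("--bfile and --out are required")
  }

  study <- read_plink(opt$bfile)
  phen <- NULL
  if (!is.null(opt$pheno)) {
    if (is.null(opt$pheno_name)) stop("--pheno requires --pheno-name")
    raw <- read_pheno_covar(study, opt$pheno, opt$pheno_name)[, 1]
    phen <- ifelse(raw %in% c(0, 1), raw, ifelse(raw == 2, 1, NA))
  }
  covar <- NULL
  if (!is.null(opt$covar)) {
    if (is.null(opt$covar_names)) stop("--covar requires --covar-names")
    cols <- strsplit(opt$covar_names, ",")[[1]]
    covar <- read_pheno_covar(study, opt$covar, cols)
  }
  if (!is.null(opt$seed)) set.seed(opt$seed)

  terms <- term_spec(opt$test, interaction_covar = opt$interaction_covar)
  methods <- strsplit(opt$method, ",")[[1]]
  res <- gwas_scan(study, methods = methods, terms = terms,
                   covariates = covar, phenotype = phen,
                   coding = opt$coding)
  write_results(res, opt$out)
  message(sprintf(
    "scan: %d markers x %d method(s); %d individuals used, %d excluded; %d null fit(s)",
    study$marker_count, length(methods), attr(res, "n_used"),
    attr(res, "n_excluded"), attr(res, "null_fits")))
  n_hits <- sum(!is.na(res$P) & res$P < 5e-8)
  if (n_hits > 0) {
    message(sprintf("scan: %d row(s) below genome-wide 5e-08", n_hits))
  }
  invisible(res)
}
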