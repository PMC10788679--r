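#' Model-based imputation quality metric (Rsq)
#'
#' Rsq is the ratio between the observed variance of the imputed dosages and
#' the binomial variance expected under Hardy-Weinberg at the alternative
#' allele frequency `p`: `Var(y) / (p (1 - p))` for haploid dosages (HDS in
#' `[0, 1]`) and `Var(y) / (2 p (1 - p))` for diploid dosages (DS in
#' `[0, 2]`).  Variances use divisor `n` (population variance), so the
#' decomposition identities of [decompose_metrics()] hold exactly.
#'
#' @param y numeric vector of imputed dosages.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param p optional allele-frequency override; by default the AAF of the
#'   imputed dosages, `mean(y) / max dose`, is used.
#' @return A single nonnegative number, or `NA` (with a `flag` attribute
#'   `"monomorphic_imputed"`) when `p` is 0 or 1.
#' @examples
#' compute_rsq(c(0.1, 0.2, 0.8, 0.9)) # 0.5
#' @export
compute_rsq <- function(y, ploidy = c("haploid", "diploid"), p = NULL) {
  ploidy <- match.arg(ploidy)
  check_dosage_vector(y, ploidy)
  dose <- if (ploidy == "haploid") 1 else 2
  if (is.null(p)) p <- mean(y) / dose
  stopifnot_scalar_number(p, "p")
  if (p <= 0 || p >= 1) {
    return(structure(NA_real_, flag = "monomorphic_imputed"))
  }
  var_pop(y) / (dose * p * (1 - p))
}

#' Empirical dosage r-squared (EmpRsq)
#'
#' The squared Pearson correlation between the true allele (or genotype dose)
#' `x` and the imputed dosage `y`; equivalently the ratio of the regression
#' sum of squares to the total sum of squares in the simple linear regression
#' of `y` on `x`.  This is the "true" imputation accuracy, often written
#' dosage r2.
#'
#' @param x integer-valued true alleles (haploid, in \{0, 1\}) or genotype
#'   doses (diploid, in \{0, 1, 2\}).
#' @param y imputed dosages, same length and ploidy as `x`.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return A number in `[0, 1]`; `NA` with a `flag` attribute
#'   (`"monomorphic_true"` or `"monomorphic_imputed"`) when either vector has
#'   zero variance.  When `x` and `y` are negatively correlated the result
#'   carries attribute `negative_slope = TRUE`: the squared correlation
#'   discards the sign, and the downstream `beta_imp` is not defined there.
#' @examples
#' compute_emprsq(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)) # 0.98
#' @export
compute_emprsq <- function(x, y, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  check_allele_vector(x, ploidy)
  check_dosage_vector(y, ploidy)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  vx <- var_pop(x)
  vy <- var_pop(y)
  if (vx == 0) return(structure(NA_real_, flag = "monomorphic_true"))
  if (vy == 0) return(structure(NA_real_, flag = "monomorphic_imputed"))
  cv <- cov_pop(x, y)
  out <- min(cv^2 / (vx * vy), 1)  # guard the fp edge of perfect correlation
  if (cv < 0) attr(out, "negative_slope") <- TRUE
  out
}

#' MAF-adjusted residual error (MARE)
#'
#' The residual-variance component of Rsq: `MARE = (1 - EmpRsq) * Rsq`,
#' i.e. `SS_res / n` scaled by the binomial variance.  MARE is elevated when
#' confidently wrong dosages inflate Rsq.
#'
#' @param rsq nonnegative Rsq value.
#' @param emprsq EmpRsq value in `[0, 1]`.
#' @return `(1 - emprsq) * rsq`, vectorized over its arguments.
#' @export
compute_mare <- function(rsq, emprsq) {
  check_metric_pair(rsq, emprsq)
  (1 - emprsq) * rsq
}

#' Imputation regression slope component (beta_imp)
#'
#' `beta_imp = sqrt(EmpRsq * Rsq)`: under equal allele frequencies in truth
#' and dosages this equals the slope of the regression of imputed dosage on
#' true genotype, and measures how distinguishable the dosage groups of the
#' true genotypes are.  Only the nonnegative branch is defined; negatively
#' correlated dosages are flagged upstream and reported as missing.
#'
#' @inheritParams compute_mare
#' @return `sqrt(emprsq * rsq)`, vectorized.
#' @export
compute_beta_imp <- function(rsq, emprsq) {
  check_metric_pair(rsq, emprsq)
  sqrt(emprsq * rsq)
}

#' Decompose the quality metrics of one variant
#'
#' Computes Rsq, EmpRsq, MARE and beta_imp for a paired truth/dosage vector,
#' together with the raw regression slope `Cov(x, y) / Var(x)` as a
#' diagnostic.  Undefined metrics (monomorphic truth or dosages, negative
#' correlation) are reported as `NA` with an explanatory flag, never dropped.
#'
#' @inheritParams compute_emprsq
#' @param variant optional list or one-row data frame with `chrom`, `pos`,
#'   `ref`, `alt` identifying the variant.
#' @param p optional AAF override passed to [compute_rsq()].
#' @return A one-row `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `aaf`, `maf`, `rsq`, `emprsq`, `mare`, `beta_imp`, `slope`, `n`, `flags`.
#' @examples
#' decompose_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
#' @export
decompose_metrics <- function(x, y, ploidy = c("haploid", "diploid"),
                              variant = NULL, p = NULL) {
  ploidy <- match.arg(ploidy)
  check_allele_vector(x, ploidy)
  check_dosage_vector(y, ploidy)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  dose <- if (ploidy == "haploid") 1 else 2
  aaf <- if (is.null(p)) mean(y) / dose else p
  rsq <- compute_rsq(y, ploidy, p = p)
  emprsq <- compute_emprsq(x, y, ploidy)
  flags <- character(0)
  if (is.na(rsq)) flags <- c(flags, attr(rsq, "flag"))
  if (is.na(emprsq)) flags <- c(flags, attr(emprsq, "flag"))
  neg <- isTRUE(attr(emprsq, "negative_slope"))
  if (neg) flags <- c(flags, "negative_slope")
  flags <- unique(flags)
  vx <- var_pop(x)
  slope <- if (vx > 0) cov_pop(x, y) / vx else NA_real_
  ok <- !is.na(rsq) && !is.na(emprsq)
  mare <- if (ok) compute_mare(as.numeric(rsq), as.numeric(emprsq)) else NA_real_
  beta <- if (ok && !neg) {
    compute_beta_imp(as.numeric(rsq), as.numeric(emprsq))
  } else {
    NA_real_
  }
  data.frame(
    chrom = if (is.null(variant)) NA_character_ else as.character(variant$chrom),
    pos = if (is.null(variant)) NA_integer_ else as.integer(variant$pos),
    ref = if (is.null(variant)) NA_character_ else as.character(variant$ref),
    alt = if (is.null(variant)) NA_character_ else as.character(variant$alt),
    aaf = aaf,
    maf = min(aaf, 1 - aaf),
    rsq = as.numeric(rsq),
    emprsq = as.numeric(emprsq),
    mare = mare,
    beta_imp = beta,
    slope = slope,
    n = length(y),
    flags = if (length(flags)) paste(flags, collapse = ";") else "ok",
    stringsAsFactors = FALSE
  )
}

#' Decompose quality metrics for a matrix of variants
#'
#' Row-wise application of [decompose_metrics()] to a truth matrix and a
#' dosage matrix (markers by haplotypes/individuals), vectorized for speed.
#'
#' @param truth integer matrix of true alleles (markers x haplotypes).
#' @param dosage numeric matrix of imputed dosages, same dimensions.
#' @param markers optional data frame with `chrom`, `pos`, `ref`, `alt` rows
#'   matching the matrix rows.
#' @inheritParams compute_emprsq
#' @return A `data.frame` with one row per marker, columns as in
#'   [decompose_metrics()].
#' @export
decompose_matrix <- function(truth, dosage, ploidy = c("haploid", "diploid"),
                             markers = NULL) {
  ploidy <- match.arg(ploidy)
  if (!is.matrix(truth) || !is.matrix(dosage) ||
      !all(dim(truth) == dim(dosage))) {
    stop("`truth` and `dosage` must be matrices of equal dimension",
         call. = FALSE)
  }
  dose <- if (ploidy == "haploid") 1 else 2
  n <- ncol(truth)
  mx <- rowMeans(truth)
  my <- rowMeans(dosage)
  vx <- pmax(rowMeans(truth * truth) - mx^2, 0)
  vy <- pmax(rowMeans(dosage * dosage) - my^2, 0)
  cv <- rowMeans(truth * dosage) - mx * my
  aaf <- my / dose
  denom <- dose * aaf * (1 - aaf)
  rsq <- ifelse(aaf > 0 & aaf < 1, vy / denom, NA_real_)
  emprsq <- ifelse(vx > 0 & vy > 0, pmin(cv^2 / (vx * vy), 1), NA_real_)
  neg <- !is.na(emprsq) & cv < 0
  ok <- !is.na(rsq) & !is.na(emprsq)
  mare <- ifelse(ok, (1 - emprsq) * rsq, NA_real_)
  beta <- ifelse(ok & !neg, sqrt(emprsq * rsq), NA_real_)
  flags <- rep("ok", length(rsq))
  flags[vy == 0 | !(aaf > 0 & aaf < 1)] <- "monomorphic_imputed"
  flags[vx == 0] <- "monomorphic_true"
  flags[vx == 0 & (vy == 0 | !(aaf > 0 & aaf < 1))] <-
    "monomorphic_true;monomorphic_imputed"
  flags[neg] <- paste0(flags[neg], ";negative_slope")
  flags <- sub("^ok;", "", flags)
  data.frame(
    chrom = if (is.null(markers)) NA_character_ else as.character(markers$chrom),
    pos = if (is.null(markers)) NA_integer_ else as.integer(markers$pos),
    ref = if (is.null(markers)) NA_character_ else as.character(markers$ref),
    alt = if (is.null(markers)) NA_character_ else as.character(markers$alt),
    aaf = aaf,
    maf = pmin(aaf, 1 - aaf),
    rsq = rsq,
    emprsq = emprsq,
    mare = mare,
    beta_imp = beta,
    slope = ifelse(vx > 0, cv / vx, NA_real_),
    n = n,
    flags = flags,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Theoretical MARE and beta_imp surfaces
#'
#' Evaluates `MARE = (1 - EmpRsq) Rsq` and `beta_imp = sqrt(EmpRsq Rsq)` on a
#' grid, for isoline diagnostics on the (dosage r2, Rsq) plane: a variant's
#' position relative to the diagonal, together with these surfaces, reveals
#' the shape of its imputed-dosage distribution.
#'
#' @param rsq_grid numeric vector of Rsq values (nonnegative).
#' @param emprsq_grid numeric vector of EmpRsq values in `[0, 1]`.
#' @return A long-format `data.frame` with columns `rsq`, `emprsq`, `mare`,
#'   `beta_imp`.
#' @export
theoretical_surfaces <- function(rsq_grid, emprsq_grid) {
  if (any(rsq_grid < 0) || any(emprsq_grid < 0 | emprsq_grid > 1)) {
    stop("grids must satisfy rsq >= 0 and 0 <= emprsq <= 1", call. = FALSE)
  }
  g <- expand.grid(rsq = rsq_grid, emprsq = emprsq_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$mare <- compute_mare(g$rsq, g$emprsq)
  g$beta_imp <- compute_beta_imp(g$rsq, g$emprsq)
  g
}

check_allele_vector <- function(x, ploidy) {
  if (length(x) < 2) stop("allele vector needs length >= 2", call. = FALSE)
  top <- if (ploidy == "haploid") 1 else 2
  if (anyNA(x) || any(x != round(x)) || any(x < 0 | x > top)) {
    stop(sprintf("true alleles must be integers in 0..%d", top), call. = FALSE)
  }
  invisible(x)
}

check_dosage_vector <- function(y, ploidy) {
  if (length(y) < 2) stop("dosage vector needs length >= 2", call. = FALSE)
  top <- if (ploidy == "haploid") 1 else 2
  if (anyNA(y) || any(y < 0 | y > top)) {
    stop(sprintf("dosages must lie in [0, %d]", top), call. = FALSE)
  }
  invisible(y)
}

check_metric_pair <- function(rsq, emprsq) {
  if (anyNA(rsq) || anyNA(emprsq) || any(rsq < 0) ||
      any(emprsq < 0 | emprsq > 1)) {
    stop("need rsq >= 0 and emprsq in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}
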