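#' Phased reference haplotype panel
#'
#' Container for a markers-by-haplotypes binary allele matrix with marker
#' metadata and optional per-haplotype ancestry labels.
#'
#' @param alleles integer matrix (markers x haplotypes) with entries 0 (ref)
#'   or 1 (alt).
#' @param markers optional data frame with columns `chrom`, `pos` (1-based,
#'   strictly increasing within a chromosome), `id`, `ref`, `alt`; a default
#'   ladder of synthetic SNVs is generated when omitted.
#' @param ancestry optional character vector of per-haplotype labels.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, markers = NULL, ancestry = NULL) {
  if (!is.matrix(alleles) || ncol(alleles) < 1) {
    stop("`alleles` must be a matrix with at least one haplotype",
         call. = FALSE)
  }
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
    stop("panel alleles must be 0/1 with no missing values", call. = FALSE)
  }
  storage.mode(alleles) <- "integer"
  m <- nrow(alleles)
  if (is.null(markers)) {
    markers <- data.frame(
      chrom = "1", pos = seq_len(m) * 1000L,
      id = sprintf("snv%d", seq_len(m)),
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
  }
  if (nrow(markers) != m) {
    stop("`markers` must have one row per matrix row", call. = FALSE)
  }
  sp <- split(markers$pos, markers$chrom)
  if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("marker positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  if (!is.null(ancestry) && length(ancestry) != ncol(alleles)) {
    stop("`ancestry` must have one label per haplotype", call. = FALSE)
  }
  structure(
    list(alleles = alleles, markers = markers, ancestry = ancestry),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d markers x %d haplotypes\n",
              nrow(x$alleles), ncol(x$alleles)))
  if (!is.null(x$ancestry)) {
    tb <- table(x$ancestry)
    cat("  ancestry:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Li-Stephens HMM parameter set
#'
#' Per-interval template switching rates `theta` (probability that the
#' copying template jumps between two adjacent markers; the jump lands
#' uniformly on all `H` panel haplotypes, including the current one) and
#' per-marker error rates `epsilon` (probability of observing an allele that
#' differs from the copied template).  Values are clamped to the open unit
#' interval / `(1e-6, 0.49)` so the recursions stay nondegenerate.
#'
#' @param theta numeric vector, length one less than the marker count, each
#'   in (0, 1).
#' @param epsilon numeric vector of per-marker error rates in (0, 0.5), or a
#'   single value to be recycled.
#' @param n_markers marker count (needed to recycle a scalar `epsilon` and to
#'   validate lengths).
#' @param provenance one of `"estimated"`, `"genetic_map"`, `"manual"`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(theta, epsilon = 1e-3, n_markers = length(theta) + 1L,
                       provenance = c("manual", "estimated", "genetic_map")) {
  provenance <- match.arg(provenance)
  if (n_markers < 1) stop("need at least one marker", call. = FALSE)
  if (length(theta) != n_markers - 1L) {
    stop("`theta` must have length n_markers - 1", call. = FALSE)
  }
  if (length(epsilon) == 1L) epsilon <- rep(epsilon, n_markers)
  if (length(epsilon) != n_markers) {
    stop("`epsilon` must have length n_markers (or 1)", call. = FALSE)
  }
  if (anyNA(theta) || anyNA(epsilon)) {
    stop("parameters must not be missing", call. = FALSE)
  }
  theta <- clamp(theta, .THETA_FLOOR, .THETA_CEIL)
  epsilon <- clamp(epsilon, .EPS_FLOOR, .EPS_CEIL)
  structure(
    list(theta = as.numeric(theta), epsilon = as.numeric(epsilon),
         provenance = provenance),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "<hmm_params> %d intervals (provenance: %s)\n  total theta %.4g, mean epsilon %.3g\n",
    length(x$theta), x$provenance, sum(x$theta), mean(x$epsilon)
  ))
  invisible(x)
}

#' Typed-marker mask
#'
#' @param typed logical vector, `TRUE` at markers observed on the simulated
#'   genotyping array.
#' @return The validated logical vector.
#' @export
typed_mask <- function(typed) {
  if (!is.logical(typed) || anyNA(typed)) {
    stop("`typed` must be a logical vector without NA", call. = FALSE)
  }
  if (!any(typed)) stop("at least one marker must be typed", call. = FALSE)
  typed
}

check_hmm_inputs <- function(target, panel, params, mask) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(params, "hmm_params"))
  m <- nrow(panel$alleles)
  if (length(params$theta) != m - 1L || length(params$epsilon) != m) {
    stop("parameter lengths do not match the panel", call. = FALSE)
  }
  mask <- typed_mask(mask)
  if (length(mask) != m) {
    stop("mask length does not match the panel", call. = FALSE)
  }
  if (length(target) != m) {
    stop("target must supply one entry per panel marker (NA where untyped)",
         call. = FALSE)
  }
  if (any(!is.na(target) & !(target %in% c(0, 1)))) {
    stop("target alleles must be 0, 1 or NA", call. = FALSE)
  }
  if (all(is.na(target[mask]))) {
    stop("target has no observed allele at any typed marker", call. = FALSE)
  }
  if (as.double(m) * ncol(panel$alleles) > 1.5e8) {
    stop("problem exceeds the supported single-region size ",
         "(~1e5 markers x 1e3 haplotypes); split the region", call. = FALSE)
  }
  mask
}

# Encode observation vector for the C++ core: -1 (NA) = no emission.
encode_target <- function(target, mask) {
  obs <- rep(NA_integer_, length(target))
  obs[mask] <- as.integer(target[mask])
  obs
}

#' Forward-backward posterior copying probabilities
#'
#' Runs the scaled forward-backward recursions of the Li-Stephens
#' haplotype-copying HMM for one target haplotype and returns the posterior
#' probability that the target copies each panel haplotype at each marker.
#' Rows sum to one.  Per-marker rescaling keeps the recursion stable for
#' regions of 1e5 markers and more.
#'
#' @param target integer vector of observed target alleles, one entry per
#'   panel marker; entries at untyped markers are ignored and `NA` at a typed
#'   marker means missing (no emission there).
#' @param panel a [haplotype_panel()].
#' @param params an [hmm_params()] whose lengths match the panel.
#' @param mask logical typed-marker mask (see [typed_mask()]).
#' @return A list with `posterior` (markers x haplotypes), `loo_posterior`
#'   (same, with each marker's own emission removed -- the leave-one-out
#'   posterior), and `loglik`.
#' @export
ls_forward_backward <- function(target, panel, params, mask) {
  mask <- check_hmm_inputs(target, panel, params, mask)
  r <- ls_fb_cpp(panel$alleles, encode_target(target, mask),
                 params$theta, params$epsilon, TRUE)
  list(posterior = r$posterior, loo_posterior = r$loo_posterior,
       loglik = r$loglik)
}

#' Impute haploid dosages for one target haplotype
#'
#' The haploid dosage (HDS) at a marker is the posterior-weighted mean of the
#' panel alleles: `HDS(m) = sum_h P(copy h at m) * allele(m, h)`, in
#' `[0, 1]`.
#'
#' @inheritParams ls_forward_backward
#' @return Numeric vector of HDS values, one per marker.
#' @export
ls_impute <- function(target, panel, params, mask) {
  mask <- check_hmm_inputs(target, panel, params, mask)
  ls_fb_cpp(panel$alleles, encode_target(target, mask),
            params$theta, params$epsilon, FALSE)$hds
}

#' Leave-one-out dosages at typed markers
#'
#' For each typed marker the HDS is recomputed with that marker's own
#' emission removed while every other typed marker stays observed --
#' equivalent to re-running the imputation with only that marker hidden, and
#' the standard way to score imputation accuracy at array sites without
#' external truth.  At untyped markers the value equals the ordinary imputed
#' dosage.
#'
#' @inheritParams ls_forward_backward
#' @return Numeric vector of leave-one-out HDS values, one per marker.
#' @export
loo_dosage <- function(target, panel, params, mask) {
  mask <- check_hmm_inputs(target, panel, params, mask)
  ls_fb_cpp(panel$alleles, encode_target(target, mask),
            params$theta, params$epsilon, FALSE)$loo_hds
}

#' Impute a matrix of target haplotypes
#'
#' Convenience driver applying [ls_impute()] / [loo_dosage()] to each column
#' of a target allele matrix.
#'
#' @param targets integer matrix (markers x target haplotypes) of observed
#'   alleles; only rows where `mask` is `TRUE` are used.
#' @inheritParams ls_forward_backward
#' @return An object of class `dosage_set`: list with `hds` and `loo_hds`
#'   (markers x target haplotypes).  Pair columns with [diploid_dosage()] to
#'   obtain DS.
#' @export
impute_matrix <- function(targets, panel, params, mask) {
  if (!is.matrix(targets)) stop("`targets` must be a matrix", call. = FALSE)
  m <- nrow(panel$alleles)
  if (nrow(targets) != m) {
    stop("`targets` must have one row per panel marker", call. = FALSE)
  }
  hds <- matrix(NA_real_, m, ncol(targets))
  loo <- matrix(NA_real_, m, ncol(targets))
  for (j in seq_len(ncol(targets))) {
    mk <- check_hmm_inputs(targets[, j], panel, params, mask)
    r <- ls_fb_cpp(panel$alleles, encode_target(targets[, j], mk),
                   params$theta, params$epsilon, FALSE)
    hds[, j] <- r$hds
    loo[, j] <- r$loo_hds
  }
  colnames(hds) <- colnames(targets)
  colnames(loo) <- colnames(targets)
  structure(list(hds = hds, loo_hds = loo), class = "dosage_set")
}

#' Diploid dosages from paired haploid dosages
#'
#' @param hds markers x haplotypes HDS matrix with an even number of columns;
#'   columns `2i - 1` and `2i` are the two haplotypes of individual `i`.
#' @return markers x individuals DS matrix in `[0, 2]`.
#' @export
diploid_dosage <- function(hds) {
  if (!is.matrix(hds) || ncol(hds) %% 2 != 0) {
    stop("`hds` must be a matrix with an even number of columns",
         call. = FALSE)
  }
  hds[, seq(1, ncol(hds), by = 2), drop = FALSE] +
    hds[, seq(2, ncol(hds), by = 2), drop = FALSE]
}

#' Scale the template switching rates
#'
#' Multiplies every per-interval `theta` by `fold` (clamping into the open
#' unit interval), leaving `epsilon` untouched -- the manipulation used to
#' probe how the switch rate shapes dosage certainty and Rsq.
#'
#' @param params an [hmm_params()].
#' @param fold positive scaling factor.
#' @return A new `hmm_params` with provenance `"manual"`.
#' @export
scale_theta <- function(params, fold) {
  stopifnot(inherits(params, "hmm_params"))
  stopifnot_scalar_number(fold, "fold")
  if (fold <= 0) stop("`fold` must be positive", call. = FALSE)
  hmm_params(clamp(params$theta * fold, .THETA_FLOOR, .THETA_CEIL),
             params$epsilon, provenance = "manual")
}
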