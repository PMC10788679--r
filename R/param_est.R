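#' Estimate HMM parameters from a reference panel
#'
#' Leave-one-haplotype-out Baum-Welch: each panel haplotype in turn is
#' treated as a fully typed target and run through the forward-backward
#' recursions against the remaining panel; posterior template-jump
#' probabilities per interval and mismatch probabilities per marker are
#' pooled over the held-out sweeps and the M-step divides by the number of
#' sweeps.  Iterates until the largest relative parameter change drops below
#' `tol` or `max_iter` is reached.  The pooled held-out log-likelihood is
#' non-decreasing over iterations.
#'
#' @param panel a [haplotype_panel()] with at least 3 haplotypes and 2
#'   markers.
#' @param max_iter maximum EM iterations (default 20).
#' @param tol relative-change convergence tolerance (default 1e-4).
#' @param pooled if `TRUE`, fit a single switch rate shared by all intervals
#'   (useful for small panels where per-interval estimates are noisy);
#'   recorded in the returned provenance attributes.
#' @param init_theta,init_eps uniform initial values (defaults 0.01 and
#'   1e-3), fixed so runs are reproducible.
#' @return An [hmm_params()] with provenance `"estimated"` and attributes
#'   `loglik` (per-iteration held-out log-likelihood), `iterations`,
#'   `converged`, `pooled`, and `degenerate` (`TRUE` when the panel carries
#'   no information about switching, i.e. all haplotypes identical; the
#'   floor-clamped initial rates are returned in that case).
#' @export
estimate_hmm_params <- function(panel, max_iter = 20L, tol = 1e-4,
                                pooled = FALSE, init_theta = 0.01,
                                init_eps = 1e-3) {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  if (ncol(A) < 3) stop("need at least 3 haplotypes", call. = FALSE)
  if (nrow(A) < 2) stop("need at least 2 markers", call. = FALSE)
  m <- nrow(A)
  if (all(A == A[, 1])) {
    # identical haplotypes: the likelihood is flat in theta, nothing to learn
    out <- hmm_params(rep(.THETA_FLOOR, m - 1), rep(init_eps, m),
                      provenance = "estimated")
    attr(out, "degenerate") <- TRUE
    attr(out, "pooled") <- pooled
    return(out)
  }
  fit <- ls_em_cpp(A, rep(init_theta, m - 1), rep(init_eps, m),
                   as.integer(max_iter), tol, pooled,
                   .THETA_FLOOR, .THETA_CEIL, .EPS_FLOOR, .EPS_CEIL)
  out <- hmm_params(fit$theta, fit$eps, provenance = "estimated")
  attr(out, "loglik") <- fit$loglik
  attr(out, "iterations") <- fit$iterations
  attr(out, "converged") <- fit$converged
  attr(out, "pooled") <- pooled
  attr(out, "degenerate") <- FALSE
  out
}

#' Total switch rate over a region
#'
#' The sum of the per-interval template switching rates -- a summary of how
#' dissimilar the panel haplotypes are over the region (larger panels of one
#' ancestry give smaller totals; added ancestral diversity gives larger
#' ones).
#'
#' @param params an [hmm_params()].
#' @return A single nonnegative number (0 for a single-marker region).
#' @export
total_theta <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  sum(params$theta)
}

#' Read a genetic map
#'
#' @param path whitespace- or tab-delimited three-column text file
#'   (chromosome, base-pair position, cumulative cM), PLINK-style; a header
#'   line is auto-detected.
#' @return A `data.frame` with columns `chrom`, `pos`, `cm`, validated to be
#'   non-decreasing.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\S+\\s+\\d+\\s+[0-9.eE+-]+\\s*$", first)
  gm <- read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(gm) < 3) stop("genetic map needs 3 columns", call. = FALSE)
  gm <- gm[, 1:3]
  names(gm) <- c("chrom", "pos", "cm")
  genetic_map(gm$pos, gm$cm, chrom = gm$chrom)
}

#' Construct a genetic map
#'
#' @param pos base-pair positions (non-decreasing).
#' @param cm cumulative genetic distances in centimorgan (non-decreasing).
#' @param chrom chromosome label(s).
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(pos, cm, chrom = "1") {
  if (length(pos) != length(cm) || length(pos) < 2) {
    stop("need >= 2 matched (pos, cM) pairs", call. = FALSE)
  }
  if (any(diff(pos) < 0) || any(diff(cm) < 0)) {
    stop("positions and cM must be non-decreasing", call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, pos = pos, cm = cm, stringsAsFactors = FALSE),
    class = c("genetic_map", "data.frame")
  )
}

#' Switch rates from a genetic map
#'
#' Converts genetic-map distances between adjacent markers into template
#' switching rates using the fixed transform 0.01 cM = 1% switching rate,
#' i.e. `theta = delta cM` numerically, clamped into the open unit interval.
#' Marker positions off the map grid are linearly interpolated; positions
#' beyond the map ends are linearly extrapolated with the terminal segment's
#' rate (a message reports how many markers required extrapolation).
#'
#' @param map a [genetic_map()].
#' @param positions ordered (strictly increasing) marker base-pair positions.
#' @param epsilon per-marker error rate for the returned parameter set
#'   (default 1e-3).
#' @return An [hmm_params()] with provenance `"genetic_map"`.
#' @export
theta_from_genetic_map <- function(map, positions, epsilon = 1e-3) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(positions) < 2 || any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  n_out <- sum(positions < min(map$pos) | positions > max(map$pos))
  if (n_out > 0) {
    message(sprintf("%d marker(s) outside the map range; extrapolating", n_out))
  }
  cm <- interp_cm(map$pos, map$cm, positions)
  theta <- clamp(diff(cm), .THETA_FLOOR, .THETA_CEIL)
  hmm_params(theta, epsilon, provenance = "genetic_map")
}

# Piecewise-linear interpolation with linear extrapolation using the
# terminal segment slopes.
interp_cm <- function(map_pos, map_cm, pos) {
  out <- approx(map_pos, map_cm, xout = pos, ties = "ordered")$y
  k <- length(map_pos)
  lo_slope <- (map_cm[2] - map_cm[1]) / max(map_pos[2] - map_pos[1], 1)
  hi_slope <- (map_cm[k] - map_cm[k - 1]) / max(map_pos[k] - map_pos[k - 1], 1)
  below <- pos < map_pos[1]
  above <- pos > map_pos[k]
  out[below] <- map_cm[1] + (pos[below] - map_pos[1]) * lo_slope
  out[above] <- map_cm[k] + (pos[above] - map_pos[k]) * hi_slope
  out
}

#' Serialize / read an HMM parameter table
#'
#' Parameters are written as a tab-separated table with one row per marker:
#' `index`, `chrom`, `pos`, `theta` (the switch rate of the interval to the
#' *next* marker; `NA` on the last row) and `epsilon`.  The table
#' round-trips through [read_params()].
#'
#' @param params an [hmm_params()].
#' @param markers data frame with `chrom` and `pos` for each marker.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, markers, path) {
  stopifnot(inherits(params, "hmm_params"))
  m <- length(params$epsilon)
  if (nrow(markers) != m) {
    stop("`markers` must have one row per marker", call. = FALSE)
  }
  tab <- data.frame(
    index = seq_len(m), chrom = markers$chrom, pos = markers$pos,
    theta = c(params$theta, NA_real_), epsilon = params$epsilon,
    provenance = params$provenance, stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  hmm_params(tab$theta[-nrow(tab)], tab$epsilon,
             provenance = tab$provenance[1])
}
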