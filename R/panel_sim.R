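#' Simulation recipe for a multi-ancestry reference panel
#'
#' Describes a synthetic panel: a shared set of ancestral allele frequencies,
#' one or more ancestries diverged from it under the Balding-Nichols model,
#' and founder-mosaic haplotypes that carry linkage disequilibrium.
#'
#' @param n_markers number of SNVs.
#' @param ancestries list of ancestry blocks, each a list with `label`,
#'   `n_haplotypes` (panel haplotypes), `fst` (divergence from the ancestral
#'   frequencies, in `[0, 1)`), optional `n_founders` (default 20) and
#'   optional `n_targets` (held-out truth-known target haplotypes, default
#'   0).
#' @param base_freq_range ancestral allele frequencies are drawn uniformly
#'   from this range (default `c(0.02, 0.98)`).
#' @param copy_rate per-interval founder-mosaic switch probability in (0, 1).
#' @param mutation_rate per-marker allele flip probability.
#' @param seed integer seed governing every random draw.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_markers, ancestries, base_freq_range = c(0.02, 0.98),
                       copy_rate = 0.02, mutation_rate = 1e-3, seed = 1L) {
  if (n_markers < 2) stop("need at least 2 markers", call. = FALSE)
  if (!length(ancestries)) stop("need at least one ancestry", call. = FALSE)
  ancestries <- lapply(ancestries, function(a) {
    stopifnot(!is.null(a$label), !is.null(a$n_haplotypes), !is.null(a$fst))
    if (a$fst < 0 || a$fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
    if (is.null(a$n_founders)) a$n_founders <- 20L
    if (is.null(a$n_targets)) a$n_targets <- 0L
    a
  })
  if (sum(vapply(ancestries, `[[`, 0, "n_haplotypes")) < 2) {
    stop("total panel haplotypes must be >= 2", call. = FALSE)
  }
  if (copy_rate <= 0 || copy_rate >= 1) {
    stop("copy_rate must be in (0, 1)", call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("mutation_rate must be in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(n_markers = as.integer(n_markers), ancestries = ancestries,
         base_freq_range = base_freq_range, copy_rate = copy_rate,
         mutation_rate = mutation_rate, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' The standard synthetic benchmark recipe
#'
#' Two ancestries diverged at FST 0.1, 150 + 150 panel haplotypes from 20
#' founders each, 1000 markers, founder-mosaic copy rate 0.02, mutation rate
#' 1e-3, and 30 + 30 held-out target haplotypes; a 25% typed-marker array
#' mask accompanies it.  This fixed scene is what cross-module checks and
#' the experiment drivers run on by default.
#'
#' @param seed seed (default 20240113).
#' @return A `panel_spec`.
#' @export
standard_benchmark_spec <- function(seed = 20240113L) {
  panel_spec(
    n_markers = 1000L,
    ancestries = list(
      list(label = "A", n_haplotypes = 150L, fst = 0.1, n_founders = 20L,
           n_targets = 30L),
      list(label = "B", n_haplotypes = 150L, fst = 0.1, n_founders = 20L,
           n_targets = 30L)
    ),
    copy_rate = 0.02, mutation_rate = 1e-3, seed = seed
  )
}

#' Draw per-ancestry allele frequencies (Balding-Nichols)
#'
#' Each ancestry's frequency at a marker is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral frequency
#' `p`, so that `E[q] = p` and `Var[q] = F p (1 - p)`.  `F = 0` returns the
#' ancestral frequencies unchanged.
#'
#' @param base_freqs ancestral frequencies in (0, 1).
#' @param fst divergence parameter in `[0, 1)`.
#' @param seed integer seed.
#' @return Numeric vector of drawn frequencies.
#' @export
draw_ancestry_freqs <- function(base_freqs, fst, seed) {
  if (any(base_freqs <= 0 | base_freqs >= 1)) {
    stop("base frequencies must be in (0, 1)", call. = FALSE)
  }
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
  if (fst == 0) return(base_freqs)
  withr::with_seed(seed, {
    rbeta(length(base_freqs),
          base_freqs * (1 - fst) / fst,
          (1 - base_freqs) * (1 - fst) / fst)
  })
}

#' Simulate founder-mosaic haplotypes
#'
#' Each haplotype copies a founder and, between adjacent markers, switches to
#' a different founder (chosen uniformly among the others) with probability
#' `copy_rate`; copied alleles are flipped with probability `mutation_rate`.
#' The mosaic structure is what creates the linkage disequilibrium that
#' haplotype-copying imputation exploits.
#'
#' @param founders markers x founders 0/1 matrix.
#' @param copy_rate per-interval switch probability.
#' @param mutation_rate per-marker flip probability.
#' @param n number of haplotypes to generate.
#' @param seed integer seed.
#' @return markers x `n` integer matrix, with the generating founder indices
#'   attached as attribute `founder_path` (markers x `n`).
#' @export
simulate_haplotypes <- function(founders, copy_rate, mutation_rate, n, seed) {
  if (!is.matrix(founders) || ncol(founders) < 1) {
    stop("`founders` must be a matrix with >= 1 column", call. = FALSE)
  }
  m <- nrow(founders)
  k <- ncol(founders)
  withr::with_seed(seed, {
    out <- matrix(0L, m, n)
    paths <- matrix(0L, m, n)
    for (j in seq_len(n)) {
      idx <- integer(m)
      idx[1] <- sample.int(k, 1)
      if (m > 1) {
        sw <- runif(m - 1) < copy_rate
        for (i in 2:m) {
          if (sw[i - 1] && k > 1) {
            pick <- sample.int(k - 1, 1)  # uniform over the other founders
            idx[i] <- if (pick >= idx[i - 1]) pick + 1L else pick
          } else {
            idx[i] <- idx[i - 1]
          }
        }
      }
      h <- founders[cbind(seq_len(m), idx)]
      if (mutation_rate > 0) {
        flip <- runif(m) < mutation_rate
        h[flip] <- 1L - h[flip]
      }
      out[, j] <- h
      paths[, j] <- idx
    }
    storage.mode(out) <- "integer"
    attr(out, "founder_path") <- paths
    out
  })
}

#' Build a synthetic reference panel with held-out targets
#'
#' Realizes a [panel_spec()]: draws ancestral frequencies, diverges each
#' ancestry under Balding-Nichols, draws founders independently per marker
#' from the ancestry frequencies, generates founder-mosaic haplotypes, and
#' splits them into panel haplotypes and truth-known target haplotypes per
#' ancestry.  Deterministic given the spec's seed.
#'
#' @param spec a [panel_spec()].
#' @return A list with `panel` (a [haplotype_panel()] with ancestry labels),
#'   `targets` (markers x target-haplotypes matrix), `target_ancestry`
#'   (labels per target column), `base_freqs`, `ancestry_freqs`, and `spec`.
#' @export
build_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  m <- spec$n_markers
  base <- withr::with_seed(derive_seed(spec$seed, 1L), {
    runif(m, spec$base_freq_range[1], spec$base_freq_range[2])
  })
  blocks <- list()
  targets <- list()
  labels <- character(0)
  t_labels <- character(0)
  freqs <- list()
  for (i in seq_along(spec$ancestries)) {
    a <- spec$ancestries[[i]]
    q <- draw_ancestry_freqs(base, a$fst, derive_seed(spec$seed, 10L + i))
    freqs[[a$label]] <- q
    founders <- withr::with_seed(derive_seed(spec$seed, 100L + i), {
      matrix(as.integer(runif(m * a$n_founders) < q), m, a$n_founders)
    })
    total <- a$n_haplotypes + a$n_targets
    haps <- simulate_haplotypes(founders, spec$copy_rate, spec$mutation_rate,
                                total, derive_seed(spec$seed, 1000L + i))
    blocks[[i]] <- haps[, seq_len(a$n_haplotypes), drop = FALSE]
    labels <- c(labels, rep(a$label, a$n_haplotypes))
    if (a$n_targets > 0) {
      targets[[length(targets) + 1L]] <-
        haps[, a$n_haplotypes + seq_len(a$n_targets), drop = FALSE]
      t_labels <- c(t_labels, rep(a$label, a$n_targets))
    }
  }
  alleles <- do.call(cbind, blocks)
  tg <- if (length(targets)) do.call(cbind, targets) else NULL
  list(
    panel = haplotype_panel(alleles, ancestry = labels),
    targets = tg,
    target_ancestry = t_labels,
    base_freqs = base,
    ancestry_freqs = freqs,
    spec = spec
  )
}

#' Simulate target haplotypes by the copying process itself
#'
#' Generates haplotypes as Li-Stephens mosaics of the *panel* haplotypes
#' under the given switch and error rates -- i.e. exactly the generative
#' model the imputation engine assumes.  Useful for calibration checks: when
#' targets are drawn from the model used to impute, posterior dosages are
#' well calibrated and Rsq matches EmpRsq in expectation.
#'
#' @param panel a [haplotype_panel()].
#' @param params an [hmm_params()] supplying the switch and error rates.
#' @param n number of target haplotypes.
#' @param seed integer seed.
#' @return markers x `n` integer matrix of true target alleles.
#' @export
simulate_targets_ls <- function(panel, params, n, seed) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(params, "hmm_params"))
  A <- panel$alleles
  m <- nrow(A)
  h <- ncol(A)
  withr::with_seed(seed, {
    out <- matrix(0L, m, n)
    for (j in seq_len(n)) {
      idx <- integer(m)
      idx[1] <- sample.int(h, 1)
      if (m > 1) {
        jump <- runif(m - 1) < params$theta
        for (i in 2:m) {
          idx[i] <- if (jump[i - 1]) sample.int(h, 1) else idx[i - 1]
        }
      }
      al <- A[cbind(seq_len(m), idx)]
      err <- runif(m) < params$epsilon
      al[err] <- 1L - al[err]
      out[, j] <- al
    }
    out
  })
}

#' Random typed-marker (array) mask
#'
#' Samples a typed subset of the requested size uniformly at random.  Both
#' endpoint markers are always typed, so untyped sites are interpolations
#' between observed scaffold markers rather than extrapolations past the
#' region edge.
#'
#' @param n_markers number of markers.
#' @param typed_fraction fraction of markers typed (exclusive with `typed`).
#' @param typed explicit logical mask or integer index vector.
#' @param seed integer seed (required with `typed_fraction`).
#' @return Logical mask of length `n_markers`.
#' @export
mask_array <- function(n_markers, typed_fraction = NULL, typed = NULL,
                       seed = NULL) {
  if (!is.null(typed)) {
    if (is.numeric(typed)) {
      mk <- rep(FALSE, n_markers)
      mk[typed] <- TRUE
      typed <- mk
    }
    return(typed_mask(typed))
  }
  if (is.null(typed_fraction) || typed_fraction <= 0 || typed_fraction >= 1) {
    stop("`typed_fraction` must be in (0, 1)", call. = FALSE)
  }
  k <- round(typed_fraction * n_markers)
  if (k < 2) stop("mask would have fewer than 2 typed markers", call. = FALSE)
  if (is.null(seed)) stop("`seed` is required for a random mask", call. = FALSE)
  withr::with_seed(seed, {
    mk <- rep(FALSE, n_markers)
    mk[c(1L, n_markers)] <- TRUE
    interior <- setdiff(seq_len(n_markers), c(1L, n_markers))
    mk[sample(interior, k - 2L)] <- TRUE
    mk
  })
}

#' Flag monomorphic markers in a panel
#'
#' @param panel a [haplotype_panel()].
#' @return Logical vector, `TRUE` where the combined panel is monomorphic;
#'   such markers are excluded from metric evaluation downstream.
#' @export
monomorphic_markers <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  f <- rowMeans(panel$alleles)
  f == 0 | f == 1
}
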