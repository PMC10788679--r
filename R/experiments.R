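#' Allele-frequency bin label
#'
#' Classifies a variant by minor allele frequency and count: `singleton`
#' (MAC = 1), `doubleton` (MAC = 2), `rare` (0.1% < MAF < 0.5%),
#' `low_frequency` (0.5% <= MAF < 5%), `common` (MAF >= 5%); anything else
#' (MAF <= 0.1% with MAC > 2) is `other`.  MAC rules take precedence for
#' MAC <= 2.
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param mac minor allele count, consistent with `maf`.
#' @return Character vector of bin labels.
#' @export
maf_bin <- function(maf, mac) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("`maf` must lie in [0, 0.5]", call. = FALSE)
  }
  if (any(mac < 0 | mac != round(mac), na.rm = TRUE)) {
    stop("`mac` must be a nonnegative integer count", call. = FALSE)
  }
  if (any(mac > 0 & maf == 0, na.rm = TRUE) ||
      any(mac == 0 & maf > 0, na.rm = TRUE)) {
    stop("`maf` and `mac` disagree about monomorphism", call. = FALSE)
  }
  out <- rep("other", length(maf))
  out[maf > 0.001 & maf < 0.005] <- "rare"
  out[maf >= 0.005 & maf < 0.05] <- "low_frequency"
  out[maf >= 0.05] <- "common"
  out[mac == 2] <- "doubleton"
  out[mac == 1] <- "singleton"
  out[is.na(maf) | is.na(mac)] <- NA_character_
  out
}

#' Count confident alleles
#'
#' Number of imputed alleles with haploid dosage strictly above the
#' threshold (default `HDS > 0.9`), over all variant-by-haplotype cells.
#'
#' @param hds numeric matrix or vector of haploid dosages in `[0, 1]`.
#' @param threshold strict lower threshold (default 0.9).
#' @return Integer count.
#' @export
count_confident_alleles <- function(hds, threshold = 0.9) {
  if (length(hds) == 0) return(0L)
  if (any(hds < 0 | hds > 1, na.rm = TRUE)) {
    stop("HDS must lie in [0, 1]", call. = FALSE)
  }
  sum(hds > threshold, na.rm = TRUE)
}

#' Count high-Rsq variants
#'
#' Number of metric records with `Rsq` strictly above the threshold (default
#' 0.7; a threshold of 0.3 implements the conventional pre-analysis filter).
#' Records with missing `Rsq` are excluded; their count is attached as
#' attribute `n_missing`.
#'
#' @param records metric table with an `rsq` column.
#' @param threshold strict lower threshold (default 0.7).
#' @return Integer count with attribute `n_missing`.
#' @export
count_high_rsq <- function(records, threshold = 0.7) {
  rsq <- records$rsq
  n_missing <- sum(is.na(rsq))
  if (n_missing > 0) {
    warning(sprintf("%d record(s) with missing Rsq excluded from the count",
                    n_missing), call. = FALSE)
  }
  structure(sum(rsq > threshold, na.rm = TRUE), n_missing = n_missing)
}

#' Binned bootstrap of the Rsq - EmpRsq deviation
#'
#' Groups unflagged records into bins of the chosen metric (width 0.05 by
#' default), and within each bin resamples variants with replacement `B`
#' times to obtain the mean and the 2.5% / 97.5% empirical quantiles of the
#' bin mean of `Rsq - EmpRsq`.
#'
#' @param records metric table (from [decompose_matrix()]).
#' @param bin_metric `"emprsq"` (dosage-r2 bins) or `"rsq"`.
#' @param width bin width (default 0.05); bins are `[k w, (k + 1) w)`.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed; results are deterministic given it.
#' @return A `data.frame` with one row per nonempty bin: `bin_lower`,
#'   `bin_upper`, `n`, `mean_dev`, `q025`, `q975`.
#' @export
bin_and_bootstrap <- function(records, bin_metric = c("emprsq", "rsq"),
                              width = 0.05, B = 1000L, seed = 1L) {
  bin_metric <- match.arg(bin_metric)
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  keep <- records$flags == "ok" & !is.na(records$rsq) & !is.na(records$emprsq)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no unflagged records to bin", call. = FALSE)
  dev <- rec$rsq - rec$emprsq
  idx <- floor(rec[[bin_metric]] / width)
  withr::with_seed(seed, {
    out <- lapply(sort(unique(idx)), function(k) {
      d <- dev[idx == k]
      boots <- vapply(seq_len(B), function(b) {
        mean(d[sample.int(length(d), replace = TRUE)])
      }, numeric(1))
      data.frame(bin_lower = k * width, bin_upper = (k + 1) * width,
                 n = length(d), mean_dev = mean(d),
                 q025 = unname(quantile(boots, 0.025)),
                 q975 = unname(quantile(boots, 0.975)))
    })
    do.call(rbind, out)
  })
}

# Metric table for one evaluation surface, annotated with truth-based MAF
# bins.  Flagged records keep their row (binning callers exclude them).
evaluate_records <- function(truth, hds, markers = NULL) {
  rec <- decompose_matrix(truth, hds, markers = markers)
  n <- ncol(truth)
  af <- rowMeans(truth)
  mac <- pmin(rowSums(truth), n - rowSums(truth))
  rec$maf_true <- pmin(af, 1 - af)
  rec$mac_true <- as.integer(round(mac))
  rec$bin <- maf_bin(rec$maf_true, rec$mac_true)
  rec
}

summarize_records <- function(rec, keep = NULL) {
  if (!is.null(keep)) rec <- rec[keep, , drop = FALSE]
  ok <- rec$flags == "ok"
  rec <- rec[ok, , drop = FALSE]
  groups <- c(list(all = rec), split(rec, rec$bin))
  out <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    data.frame(bin = g, n = nrow(r),
               mean_rsq = mean(r$rsq), mean_emprsq = mean(r$emprsq),
               mean_mare = mean(r$mare), mean_beta_imp = mean(r$beta_imp),
               mean_dev = mean(r$rsq - r$emprsq),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the switch-rate scaling experiment
#'
#' For each scaling fold: scale the per-interval switch rates, impute every
#' target haplotype, and evaluate two surfaces -- leave-one-out dosages at
#' typed markers (the default accuracy surface, no external truth needed)
#' and ordinary imputed dosages at untyped markers against the held-out
#' truth.  Reports MAF-stratified means of the four metrics, the deviation
#' `Rsq - EmpRsq`, and the confident-allele / high-Rsq counts.  Summary
#' means for each fold cover that fold's unflagged records, mirroring how
#' per-run means are reported for real imputation runs; flagged records are
#' excluded and their counts retained in the per-variant tables.
#'
#' @param panel a [haplotype_panel()].
#' @param targets markers x haplotypes matrix of true target alleles.
#' @param mask logical typed-marker mask.
#' @param params baseline [hmm_params()] (fold 1).
#' @param folds positive scaling factors (default
#'   `c(0.01, 0.1, 0.5, 1, 2, 10, 100)`); `theta_fold_grid()` gives the full
#'   21-fold grid.
#' @param keep_records if `TRUE`, attach the per-fold per-variant metric
#'   tables.
#' @return An object of class `experiment_result`: list with `summary`
#'   (fold x surface x MAF-bin means), `counts` (per-fold confident-allele
#'   and high-Rsq counts), and optionally `records`.
#' @export
run_theta_scaling <- function(panel, targets, mask, params,
                              folds = c(0.01, 0.1, 0.5, 1, 2, 10, 100),
                              keep_records = FALSE) {
  if (any(folds <= 0)) stop("folds must be positive", call. = FALSE)
  mask <- typed_mask(mask)
  recs_typed <- list()
  recs_untyped <- list()
  counts <- data.frame()
  for (f in folds) {
    ds <- impute_matrix(targets, panel, scale_theta(params, f), mask)
    key <- sprintf("fold_%g", f)
    recs_typed[[key]] <- evaluate_records(
      targets[mask, , drop = FALSE], ds$loo_hds[mask, , drop = FALSE],
      panel$markers[mask, , drop = FALSE])
    recs_untyped[[key]] <- evaluate_records(
      targets[!mask, , drop = FALSE], ds$hds[!mask, , drop = FALSE],
      panel$markers[!mask, , drop = FALSE])
    all_rec <- rbind(recs_typed[[key]], recs_untyped[[key]])
    counts <- rbind(counts, data.frame(
      fold = f,
      confident_alleles = count_confident_alleles(ds$hds),
      high_rsq = as.integer(suppressWarnings(count_high_rsq(all_rec)))
    ))
  }
  summary <- do.call(rbind, lapply(seq_along(folds), function(i) {
    key <- sprintf("fold_%g", folds[i])
    rbind(
      cbind(fold = folds[i], surface = "loo_typed",
            summarize_records(recs_typed[[key]])),
      cbind(fold = folds[i], surface = "truth_untyped",
            summarize_records(recs_untyped[[key]]))
    )
  }))
  out <- list(summary = summary, counts = counts, folds = folds)
  if (keep_records) {
    out$records <- list(loo_typed = recs_typed, truth_untyped = recs_untyped)
  }
  class(out) <- "experiment_result"
  out
}

#' The full 21-fold scaling grid
#'
#' Twenty-one log-spaced scaling factors spanning 0.01 to 100.
#'
#' @return Numeric vector of length 21.
#' @export
theta_fold_grid <- function() {
  round(10^seq(-2, 2, length.out = 21), 4)
}

#' Classify ancestry-specific variants
#'
#' A variant is specific to an ancestry block when its alternate allele is
#' carried only by haplotypes of that block; variants carried by several
#' blocks are `shared`, and variants with no alternate allele are `none`.
#'
#' @param panel a [haplotype_panel()] with ancestry labels.
#' @return Character vector, one label per marker.
#' @export
ancestry_specific_variants <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(panel$ancestry)) {
    stop("panel carries no ancestry labels", call. = FALSE)
  }
  labs <- unique(panel$ancestry)
  carried <- vapply(labs, function(l) {
    rowSums(panel$alleles[, panel$ancestry == l, drop = FALSE]) > 0
  }, logical(nrow(panel$alleles)))
  k <- rowSums(carried)
  out <- rep("shared", nrow(panel$alleles))
  out[k == 0] <- "none"
  one <- which(k == 1)
  out[one] <- labs[apply(carried[one, , drop = FALSE], 1, which)]
  out
}

#' Run a panel-composition experiment
#'
#' For each scenario: build the synthetic panel, estimate the HMM parameters
#' by EM, record the total switch rate, impute the scenario's target
#' haplotypes, and evaluate the same two surfaces as
#' [run_theta_scaling()], plus counts restricted to ancestry-specific
#' variants.
#'
#' @param scenarios named list; each element is a list with `spec` (a
#'   [panel_spec()]), `target_label` (which ancestry's held-out haplotypes to
#'   impute; default all), `typed_fraction` (default 0.25) and optionally
#'   `params` (skip estimation and use these).
#' @param seed integer seed for the array masks.
#' @param em_iter maximum EM iterations per scenario (default 10).
#' @return An `experiment_result` with per-scenario `summary`, `counts`
#'   (including ancestry-specific breakdowns) and `total_theta`.
#' @export
run_panel_composition <- function(scenarios, seed = 1L, em_iter = 10L) {
  stopifnot(length(scenarios) > 0, !is.null(names(scenarios)))
  summary <- data.frame()
  counts <- data.frame()
  tt <- data.frame()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    sim <- build_panel(sc$spec)
    params <- if (!is.null(sc$params)) {
      sc$params
    } else {
      estimate_hmm_params(sim$panel, max_iter = em_iter)
    }
    tt <- rbind(tt, data.frame(scenario = nm,
                               total_theta = total_theta(params)))
    tf <- if (is.null(sc$typed_fraction)) 0.25 else sc$typed_fraction
    mask <- mask_array(sc$spec$n_markers, typed_fraction = tf,
                       seed = derive_seed(seed, match(nm, names(scenarios))))
    sel <- if (is.null(sc$target_label)) {
      rep(TRUE, ncol(sim$targets))
    } else {
      sim$target_ancestry == sc$target_label
    }
    targets <- sim$targets[, sel, drop = FALSE]
    ds <- impute_matrix(targets, sim$panel, params, mask)
    rec_t <- evaluate_records(targets[mask, , drop = FALSE],
                              ds$loo_hds[mask, , drop = FALSE],
                              sim$panel$markers[mask, , drop = FALSE])
    rec_u <- evaluate_records(targets[!mask, , drop = FALSE],
                              ds$hds[!mask, , drop = FALSE],
                              sim$panel$markers[!mask, , drop = FALSE])
    summary <- rbind(summary,
                     cbind(scenario = nm, surface = "loo_typed",
                           summarize_records(rec_t)),
                     cbind(scenario = nm, surface = "truth_untyped",
                           summarize_records(rec_u)))
    spec_lab <- ancestry_specific_variants(sim$panel)
    all_rec <- rbind(rec_t, rec_u)
    spec_all <- c(spec_lab[mask], spec_lab[!mask])
    grp <- c(list(all = rep(TRUE, length(spec_all))),
             lapply(setNames(unique(spec_lab), unique(spec_lab)),
                    function(l) spec_all == l))
    for (g in names(grp)) {
      rws <- grp[[g]]
      counts <- rbind(counts, data.frame(
        scenario = nm, variant_group = g,
        confident_alleles = count_confident_alleles(
          rbind(ds$loo_hds[mask, , drop = FALSE],
                ds$hds[!mask, , drop = FALSE])[rws, , drop = FALSE]),
        high_rsq = as.integer(suppressWarnings(
          count_high_rsq(all_rec[rws, , drop = FALSE]))),
        n_variants = sum(rws)
      ))
    }
  }
  structure(list(summary = summary, counts = counts, total_theta = tt),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  if (!is.null(x$total_theta)) {
    cat("total theta by scenario:\n")
    print(x$total_theta, row.names = FALSE)
  }
  cat("summary (bin = all):\n")
  print(x$summary[x$summary$bin == "all", , drop = FALSE], row.names = FALSE)
  invisible(x)
}
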