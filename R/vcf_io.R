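#' Read a phased reference panel or target VCF
#'
#' Reads a VCF (plain or gzipped) into a [haplotype_panel()].  The contract
#' is strict: biallelic SNVs only, fully phased `GT` with the `|` separator,
#' positions sorted and strictly increasing per chromosome, unique
#' `chrom:pos:ref:alt` keys.  Violations abort with the offending position
#' named -- there are no partial silent loads.  Diploid samples contribute
#' two haplotype columns in file order; haploid `GT` entries contribute one.
#'
#' @param path VCF file path.
#' @param mode `"panel"` (no missing alleles allowed) or `"target"` (missing
#'   alleles `.` become `NA`).
#' @return A [haplotype_panel()]; in target mode the allele matrix may
#'   contain `NA`.
#' @export
read_panel <- function(path, mode = c("panel", "target")) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  posid <- function(i) sprintf("%s:%d", chrom[i], pos[i])
  bad <- which(is.na(alt) | grepl(",", alt))
  if (length(bad)) {
    stop(sprintf("multiallelic record at %s: split into biallelic records first",
                 posid(bad[1])), call. = FALSE)
  }
  bad <- which(nchar(ref) != 1 | nchar(alt) != 1 |
                 !ref %in% c("A", "C", "G", "T") |
                 !alt %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf("non-SNV record at %s: only biallelic SNVs are supported",
                 posid(bad[1])), call. = FALSE)
  }
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) {
      i <- which(chrom == cc)[which(diff(p) <= 0)[1] + 1L]
      stop(sprintf("unsorted or duplicated position at %s", posid(i)),
           call. = FALSE)
    }
  }
  key <- paste(chrom, pos, ref, alt, sep = ":")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate variant key %s", key[duplicated(key)][1]),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) {
    stop("VCF has no GT field or no samples", call. = FALSE)
  }
  bad <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("unphased genotype at %s (sample %s): panel/target VCFs must be phased",
                 posid(bad[1, 1]), colnames(gt)[bad[1, 2]]), call. = FALSE)
  }
  cols <- list()
  labels <- character(0)
  for (j in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    np <- lengths(parts)
    if (any(np != np[1])) {
      stop(sprintf("inconsistent ploidy for sample %s", colnames(gt)[j]),
           call. = FALSE)
    }
    for (k in seq_len(np[1])) {
      al <- vapply(parts, `[[`, "", k)
      miss <- al == "."
      if (any(miss) && mode == "panel") {
        stop(sprintf("missing allele at %s (sample %s): not allowed in panel mode",
                     posid(which(miss)[1]), colnames(gt)[j]), call. = FALSE)
      }
      if (any(!al %in% c("0", "1", "."))) {
        i <- which(!al %in% c("0", "1", "."))[1]
        stop(sprintf("invalid allele '%s' at %s", al[i], posid(i)),
             call. = FALSE)
      }
      x <- suppressWarnings(as.integer(al))
      cols[[length(cols) + 1L]] <- x
      labels <- c(labels, sprintf("%s_h%d", colnames(gt)[j], k))
    }
  }
  alleles <- do.call(cbind, cols)
  colnames(alleles) <- labels
  markers <- data.frame(chrom = chrom, pos = pos,
                        id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (mode == "panel") {
    haplotype_panel(alleles, markers)
  } else {
    # target mode: relax the no-missing invariant of the panel constructor
    p <- haplotype_panel(matrix(0L, nrow(alleles), ncol(alleles),
                                dimnames = dimnames(alleles)), markers)
    p$alleles <- alleles
    p
  }
}

vcf_meta <- function() {
  c("##fileformat=VCFv4.2",
    "##source=hapdose",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    "##FORMAT=<ID=HDS,Number=.,Type=Float,Description=\"Estimated per-haplotype alternate allele dosage\">")
}

make_fix <- function(markers) {
  cbind(CHROM = as.character(markers$chrom), POS = as.character(markers$pos),
        ID = as.character(markers$id), REF = markers$ref, ALT = markers$alt,
        QUAL = ".", FILTER = "PASS", INFO = ".")
}

#' Write a haplotype panel as a phased VCF
#'
#' Haplotype columns are paired into diploid samples (`0|1`-style `GT`); an
#' odd trailing haplotype is written as a haploid sample.  Output is
#' gzip-compressed (use a `.vcf.gz` path).
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param sample_prefix prefix for generated sample names.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, sample_prefix = "S") {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  h <- ncol(A)
  ns <- ceiling(h / 2)
  gt <- matrix("", nrow(A), ns)
  for (s in seq_len(ns)) {
    a <- A[, 2 * s - 1]
    if (2 * s <= h) {
      gt[, s] <- paste(a, A[, 2 * s], sep = "|")
    } else {
      gt[, s] <- as.character(a)
    }
  }
  gt[grepl("NA", gt)] <- NA
  colnames(gt) <- sprintf("%s%d", sample_prefix, seq_len(ns))
  write_vcfr(vcf_meta(), make_fix(panel$markers),
             cbind(FORMAT = "GT", gt), path)
}

#' Write imputed dosages as a VCF
#'
#' Emits `FORMAT = GT:DS:HDS` in the style of common imputation engines:
#' `HDS` holds the comma-joined per-haplotype dosages at three decimals,
#' `DS` their sum, and `GT` the phased hard-call (`HDS > 0.5` calls the
#' alternate allele).
#'
#' @param hds markers x haplotypes dosage matrix in `[0, 1]` with an even
#'   number of columns (two per individual).
#' @param markers data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path output path (gzip-compressed; use `.vcf.gz`).
#' @param sample_prefix prefix for generated sample names.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(hds, markers, path, sample_prefix = "S") {
  if (!is.matrix(hds) || ncol(hds) %% 2 != 0) {
    stop("`hds` must have an even number of haplotype columns", call. = FALSE)
  }
  if (nrow(markers) != nrow(hds)) {
    stop("`markers` rows must match `hds` rows", call. = FALSE)
  }
  if (any(hds < 0 | hds > 1)) stop("HDS must lie in [0, 1]", call. = FALSE)
  ns <- ncol(hds) / 2
  gt <- matrix("", nrow(hds), ns)
  for (s in seq_len(ns)) {
    h1 <- hds[, 2 * s - 1]
    h2 <- hds[, 2 * s]
    gt[, s] <- sprintf("%d|%d:%.3f:%.3f,%.3f",
                       as.integer(h1 > 0.5), as.integer(h2 > 0.5),
                       h1 + h2, h1, h2)
  }
  colnames(gt) <- sprintf("%s%d", sample_prefix, seq_len(ns))
  write_vcfr(vcf_meta(), make_fix(markers),
             cbind(FORMAT = "GT:DS:HDS", gt), path)
}

write_vcfr <- function(meta, fix, gt, path) {
  suppressPackageStartupMessages(requireNamespace("vcfR", quietly = TRUE))
  obj <- methods::new(methods::className("vcfR", "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read an imputed-dosage VCF
#'
#' @param path VCF written by [write_dosages()] (or any VCF carrying `HDS`).
#' @return A list with `hds` (markers x haplotypes), `ds` (markers x
#'   individuals) and `markers`.
#' @export
read_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  hds_str <- vcfR::extract.gt(v, element = "HDS")
  if (is.null(hds_str)) stop("VCF carries no HDS field", call. = FALSE)
  cols <- list()
  labels <- character(0)
  for (j in seq_len(ncol(hds_str))) {
    parts <- strsplit(hds_str[, j], ",", fixed = TRUE)
    np <- lengths(parts)
    for (k in seq_len(np[1])) {
      cols[[length(cols) + 1L]] <- as.numeric(vapply(parts, `[[`, "", k))
      labels <- c(labels, sprintf("%s_h%d", colnames(hds_str)[j], k))
    }
  }
  hds <- do.call(cbind, cols)
  colnames(hds) <- labels
  ds_str <- vcfR::extract.gt(v, element = "DS")
  ds <- if (!is.null(ds_str)) {
    matrix(as.numeric(ds_str), nrow(ds_str), ncol(ds_str),
           dimnames = dimnames(ds_str))
  } else {
    diploid_dosage(hds)
  }
  markers <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        id = fix[, "ID"], ref = fix[, "REF"],
                        alt = fix[, "ALT"], stringsAsFactors = FALSE)
  list(hds = hds, ds = ds, markers = markers)
}

#' Write the per-variant metric table
#'
#' Tab-separated table in the style of an imputation info file, one row per
#' variant: `CHROM POS REF ALT AAF MAF Rsq EmpRsq MARE BetaImp N FLAGS`.
#' Missing metrics are printed as `-`.
#'
#' @param records metric table from [decompose_metrics()] /
#'   [decompose_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_info_table <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.5f", x))
  tab <- data.frame(
    CHROM = ifelse(is.na(records$chrom), ".", records$chrom),
    POS = ifelse(is.na(records$pos), ".", as.character(records$pos)),
    REF = ifelse(is.na(records$ref), ".", records$ref),
    ALT = ifelse(is.na(records$alt), ".", records$alt),
    AAF = fmt(records$aaf),
    MAF = fmt(records$maf),
    Rsq = fmt(records$rsq),
    EmpRsq = fmt(records$emprsq),
    MARE = fmt(records$mare),
    BetaImp = fmt(records$beta_imp),
    N = records$n,
    FLAGS = records$flags,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
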