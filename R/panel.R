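#' Construct a genotype panel
#'
#' A genotype panel bundles a samples-by-variants allele dosage matrix with
#' variant metadata (chromosome, physical and genetic position, alleles) and
#' sample metadata (sex, case/control phenotype, covariates). Dosages count
#' copies of the variant's counted allele `a1` and are 0, 1, 2 or `NA`
#' (missing). Only autosomes (1-22) are allowed.
#'
#' @param dosages numeric matrix, samples x variants, entries in {0,1,2,NA}.
#'   After mean-dosage imputation entries may be fractional in `[0,2]`.
#' @param variants data.frame with columns `snp`, `chr`, `bp`, `a1`
#'   (counted allele), `a2` and optionally `cm` (genetic position).
#' @param samples data.frame with columns `iid`, `sex` ("male"/"female")
#'   and `phenotype` (1 = case, 0 = control, NA = unknown); further columns
#'   (e.g. principal components) are carried along as covariates.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("snp", "chr", "bp", "a1", "a2")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("iid", "sex", "phenotype") %in% names(samples)))
    stop("samples must have columns: iid, sex, phenotype")
  if (!"cm" %in% names(variants)) variants$cm <- NA_real_
  variants$chr <- normalize_chrom(variants$chr)
  if (anyNA(variants$chr))
    stop("variants restricted to autosomes 1-22; non-autosomal labels found")
  if (nrow(variants) != ncol(dosages))
    stop("ncol(dosages) must equal nrow(variants)")
  if (nrow(samples) != nrow(dosages))
    stop("nrow(dosages) must equal nrow(samples)")
  if (anyDuplicated(variants$snp)) stop("duplicate snp ids in variants")
  if (anyDuplicated(samples$iid)) stop("duplicate sample iids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(samples$iid, variants$snp)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (chr %s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(sort(unique(x$variants$chr)), collapse = ",")))
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("  missing dosages: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Allele frequency and MAF of panel variants
#'
#' Frequency of the counted allele `a1`, estimated from non-missing dosages.
#'
#' @param panel a `genotype_panel`.
#' @return named numeric vector of counted-allele frequencies (`panel_freq`)
#'   or minor allele frequencies (`panel_maf`).
#' @export
panel_freq <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' @rdname panel_freq
#' @export
panel_maf <- function(panel) {
  p <- panel_freq(panel)
  pmin(p, 1 - p)
}

#' Subset a genotype panel by variants or samples
#'
#' @param panel a `genotype_panel`.
#' @param variants snp ids or logical/integer index over variants.
#' @param samples iids or logical/integer index over samples.
#' @return the subset `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  vi <- seq_len(ncol(panel$dosages))
  si <- seq_len(nrow(panel$dosages))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, panel$variants$snp) else vi[variants]
    if (anyNA(vi)) stop("unknown variant ids in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$samples$iid) else si[samples]
    if (anyNA(si)) stop("unknown sample iids in subset")
  }
  genotype_panel(panel$dosages[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE])
}
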