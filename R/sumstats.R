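# GWAS summary statistics: reading, quality control and harmonization of
# per-SNP effects against a target variant panel.

.sumstats_cols <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p", "n")

#' Construct a summary-statistics table
#'
#' @param df data.frame with columns `snp`, `chr`, `bp`, `a1` (effect allele),
#'   `a2` (other allele), `beta`, `se`, `p`, `n`.
#' @return a `sumstats` data.frame.
#' @export
sumstats <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(.sumstats_cols, names(df))
  if (length(miss)) stop("sumstats missing columns: ", paste(miss, collapse = ", "))
  df$chr <- normalize_chrom(df$chr)
  df$a1 <- toupper(df$a1); df$a2 <- toupper(df$a2)
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Read GWAS summary statistics from a delimited file
#'
#' Column names are mapped through `col_map`; defaults follow common GWAS
#' export headers (SNP, CHR, BP, A1, A2, BETA or OR, SE, P, N). When the
#' effect column is an odds ratio it is log-transformed to a beta at load
#' time.
#'
#' @param path tab/whitespace-delimited file with a header row.
#' @param col_map named list mapping the canonical fields `snp`, `chr`, `bp`,
#'   `a1`, `a2`, `beta` (or `or`), `se`, `p`, `n` to the file's column names.
#' @return a `sumstats` data.frame.
#' @export
read_sumstats <- function(path,
                          col_map = list(snp = "SNP", chr = "CHR", bp = "BP",
                                         a1 = "A1", a2 = "A2", beta = "BETA",
                                         or = "OR", se = "SE", p = "P", n = "N")) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  pick <- function(field) {
    nm <- col_map[[field]]
    if (is.null(nm) || !nm %in% names(df)) NULL else df[[nm]]
  }
  beta <- pick("beta")
  if (is.null(beta)) {
    or <- pick("or")
    if (is.null(or)) stop("sumstats file has neither a BETA nor an OR column")
    beta <- log(or)
  }
  out <- data.frame(snp = pick("snp"), chr = pick("chr"), bp = pick("bp"),
                    a1 = pick("a1"), a2 = pick("a2"), beta = beta,
                    se = pick("se"), p = pick("p"), n = pick("n"),
                    stringsAsFactors = FALSE)
  miss <- names(out)[vapply(out, is.null, TRUE)]
  if (length(miss)) stop("sumstats file missing columns for: ",
                         paste(miss, collapse = ", "))
  sumstats(out)
}

#' Quality control of GWAS summary statistics
#'
#' Applies, in order: (invalid) records with non-ACGT single-base alleles,
#' `p` outside (0,1], `se <= 0` or `n <= 0`; (ambiguous) strand-ambiguous
#' allele pairs A/T and C/G; (duplicate) all copies of a duplicated snp id;
#' (maf) minor allele frequency in the reference panel below `maf_min`;
#' (chi2) association chi-squared `(beta/se)^2` above `chi2_max`;
#' (n_outlier) sample size outside mean +/- `n_sd` standard deviations.
#' Each record is counted against the first rule it violates.
#'
#' @param ss a `sumstats` table.
#' @param freqs named counted-allele frequencies from the target/reference
#'   panel (see [panel_freq()]); `NULL` skips the MAF rule. SNPs absent from
#'   `freqs` are not filtered by MAF.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param chi2_max maximum `(beta/se)^2` (default 80).
#' @param n_sd sample-size outlier cutoff in standard deviations (default 3).
#' @return the filtered `sumstats`; the per-rule removal counts are attached
#'   as attribute `"qc_report"` (data.frame `rule`, `n_removed`).
#' @export
qc_sumstats <- function(ss, freqs = NULL, maf_min = 0.01, chi2_max = 80, n_sd = 3) {
  stopifnot(inherits(ss, "sumstats"))
  report <- data.frame(rule = character(0), n_removed = integer(0),
                       stringsAsFactors = FALSE)
  drop_rule <- function(tab, bad, rule) {
    report <<- rbind(report, data.frame(rule = rule, n_removed = sum(bad)))
    tab[!bad, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  ss <- drop_rule(ss, !(ss$a1 %in% bases) | !(ss$a2 %in% bases) |
                    ss$a1 == ss$a2 | !is.finite(ss$p) | ss$p <= 0 | ss$p > 1 |
                    !is.finite(ss$se) | ss$se <= 0 | !is.finite(ss$n) | ss$n <= 0,
                  "invalid")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ss <- drop_rule(ss, comp[ss$a1] == ss$a2, "ambiguous")
  ss <- drop_rule(ss, ss$snp %in% ss$snp[duplicated(ss$snp)], "duplicate")
  if (!is.null(freqs)) {
    f <- freqs[ss$snp]
    maf <- pmin(f, 1 - f)
    ss <- drop_rule(ss, !is.na(maf) & maf < maf_min, "maf")
  }
  ss <- drop_rule(ss, (ss$beta / ss$se)^2 > chi2_max, "chi2")
  if (nrow(ss) > 1 && stats::sd(ss$n) > 0) {
    ss <- drop_rule(ss, abs(ss$n - mean(ss$n)) > n_sd * stats::sd(ss$n), "n_outlier")
  } else {
    report <- rbind(report, data.frame(rule = "n_outlier", n_removed = 0L))
  }
  if (!nrow(ss)) stop("no SNPs survive summary-statistics QC")
  attr(ss, "qc_report") <- report
  ss
}

#' Harmonize summary statistics to a target panel's allele orientation
#'
#' Joins on snp id. If the sumstats effect allele equals the panel's counted
#' allele (`a1`) the beta is kept; if the allele pair is swapped the beta is
#' negated; any other allele combination is dropped with reason
#' `"allele_mismatch"` (complement/strand flips are not rescued). A
#' chromosome/position disagreement between the two sources on shared ids is
#' reported with a warning.
#'
#' @param ss a QC'd `sumstats` table.
#' @param panel the target [genotype_panel()].
#' @return data.frame (class `harmonized_sumstats`) with one row per aligned
#'   SNP, in the panel's allele orientation: `snp`, `chr`, `bp`, `cm`, `a1`,
#'   `a2`, `beta`, `se`, `p`, `n`. Dropped ids and reasons are attached as
#'   attribute `"dropped"`.
#' @export
harmonize <- function(ss, panel) {
  stopifnot(inherits(ss, "sumstats"), inherits(panel, "genotype_panel"))
  v <- panel$variants
  idx <- match(ss$snp, v$snp)
  shared <- !is.na(idx)
  if (!any(shared)) stop("no overlapping SNPs between sumstats and panel")
  ss <- ss[shared, , drop = FALSE]
  pv <- v[idx[shared], , drop = FALSE]
  pos_bad <- (!is.na(ss$chr) & ss$chr != pv$chr) | (ss$bp != pv$bp)
  if (any(pos_bad))
    warning(sprintf("%d shared snp id(s) disagree on chr/bp between sumstats and panel",
                    sum(pos_bad)))
  same <- ss$a1 == pv$a1 & ss$a2 == pv$a2
  swap <- ss$a1 == pv$a2 & ss$a2 == pv$a1
  dropped <- data.frame(snp = ss$snp[!(same | swap)],
                        reason = rep("allele_mismatch", sum(!(same | swap))),
                        stringsAsFactors = FALSE)
  keep <- same | swap
  out <- data.frame(snp = ss$snp[keep], chr = pv$chr[keep], bp = pv$bp[keep],
                    cm = pv$cm[keep], a1 = pv$a1[keep], a2 = pv$a2[keep],
                    beta = ifelse(swap[keep], -ss$beta[keep], ss$beta[keep]),
                    se = ss$se[keep], p = ss$p[keep], n = ss$n[keep],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("no SNPs remain after allele harmonization")
  class(out) <- c("harmonized_sumstats", "data.frame")
  attr(out, "dropped") <- dropped
  out
}
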