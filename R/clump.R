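# LD clumping of summary statistics in genetic-distance (cM) or physical
# (kb) windows, plus HLA-fraction and gene-region enrichment summaries.

#' Clumping configuration
#'
#' @param window_cm genetic-distance half-width of the clumping window in cM
#'   (default 3): neighbors within `|delta cM| <= window_cm` of an index SNP
#'   are eligible for absorption.
#' @param window_kb physical half-width in kb for `mode = "physical"`
#'   (default 250).
#' @param r2_max LD threshold: eligible neighbors with squared dosage
#'   correlation `>= r2_max` are absorbed (default 0.1).
#' @param mode `"genetic"` (cM windows, the default) or `"physical"`.
#' @param exclude_region optional region to drop before clumping, as
#'   `c(chr, bp_start, bp_end)` (inclusive bp bounds); see [hla_region()].
#' @return a `clump_config` list.
#' @export
clump_config <- function(window_cm = 3, window_kb = 250, r2_max = 0.1,
                         mode = c("genetic", "physical"),
                         exclude_region = NULL) {
  mode <- match.arg(mode)
  # r2_max > 1 is allowed as an explicit "no absorption" setting
  stopifnot(window_cm > 0, window_kb > 0, r2_max > 0, r2_max <= 2)
  if (!is.null(exclude_region)) {
    exclude_region <- as.numeric(exclude_region)
    stopifnot(length(exclude_region) == 3, exclude_region[2] <= exclude_region[3])
  }
  structure(list(window_cm = window_cm, window_kb = window_kb, r2_max = r2_max,
                 mode = mode, exclude_region = exclude_region),
            class = "clump_config")
}

#' Default HLA exclusion region
#'
#' The extended HLA region on chromosome 6, spanning the ~8 Mb of long-range
#' LD around the classical class I-III loci.
#'
#' @param chr,start,end region coordinates (defaults chr6:25,000,000-34,000,000).
#' @return numeric `c(chr, start, end)`.
#' @export
hla_region <- function(chr = 6, start = 25e6, end = 34e6) c(chr, start, end)

.in_region <- function(chr, bp, region) {
  !is.null(region) & chr == region[1] & bp >= region[2] & bp <= region[3]
}

#' Squared LD correlation between two variants
#'
#' Squared Pearson correlation of the dosage vectors; defined as 0 when
#' either variant has zero variance.
#'
#' @param panel an imputed [genotype_panel()].
#' @param a,b snp ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(panel, a, b) {
  stopifnot(inherits(panel, "genotype_panel"))
  ia <- match(a, panel$variants$snp); ib <- match(b, panel$variants$snp)
  if (is.na(ia) || is.na(ib)) stop("variant not in panel: ", if (is.na(ia)) a else b)
  x <- panel$dosages[, ia]; y <- panel$dosages[, ib]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Greedy LD clumping with genetic-distance windows
#'
#' Candidates are ordered by ascending p-value (ties broken by position then
#' snp id). Repeatedly, the best unassigned SNP becomes an index SNP and
#' absorbs every unassigned SNP on the same chromosome that lies within the
#' window (`|delta cM| <= window_cm` in genetic mode, `|delta bp| <=
#' window_kb * 1000` in physical mode) and has `r^2 >= r2_max` with it.
#' SNPs inside `config$exclude_region` are dropped before clumping.
#'
#' @param ss a `harmonized_sumstats` table (subset of the panel's variants);
#'   genetic mode requires non-missing `cm`.
#' @param panel the imputed LD reference [genotype_panel()].
#' @param config a [clump_config()].
#' @return a `clump_result`: list with `index` (data.frame `snp`, `chr`,
#'   `bp`, `cm`, `a1`, `a2`, `beta`, `se`, `p`, `n`, `n_absorbed`, in
#'   selection order), `assignments` (data.frame `snp`, `index_snp` for
#'   absorbed SNPs) and the `config`.
#' @export
clump <- function(ss, panel, config = clump_config()) {
  stopifnot(inherits(ss, "data.frame"), inherits(panel, "genotype_panel"),
            inherits(config, "clump_config"))
  vi <- match(ss$snp, panel$variants$snp)
  if (anyNA(vi)) stop("sumstats contain SNPs absent from the LD panel")
  cand <- as.data.frame(ss)[, c("snp", "chr", "bp", "cm", "a1", "a2",
                                "beta", "se", "p", "n")]
  excluded <- character(0)
  if (!is.null(config$exclude_region)) {
    drop <- .in_region(cand$chr, cand$bp, config$exclude_region)
    excluded <- cand$snp[drop]
    cand <- cand[!drop, , drop = FALSE]
    vi <- vi[!drop]
  }
  if (!nrow(cand)) stop("no SNPs left to clump after region exclusion")
  if (config$mode == "genetic" && anyNA(cand$cm))
    stop("genetic-mode clumping requires cM annotation for every SNP")
  ord <- order(cand$p, cand$bp, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  vi <- vi[ord]
  pos <- if (config$mode == "genetic") cand$cm else cand$bp
  halfw <- if (config$mode == "genetic") config$window_cm else config$window_kb * 1000
  G <- panel$dosages
  n_cand <- nrow(cand)
  state <- integer(n_cand)          # 0 unassigned, -1 index, >0 absorbed-by row
  index_rows <- integer(0)
  n_absorbed <- integer(0)
  for (i in seq_len(n_cand)) {
    if (state[i] != 0L) next
    state[i] <- -1L
    index_rows <- c(index_rows, i)
    open <- which(state == 0L & cand$chr == cand$chr[i] &
                    abs(pos - pos[i]) <= halfw)
    if (length(open)) {
      x <- G[, vi[i]]
      if (stats::sd(x) == 0) {
        r2 <- rep(0, length(open))
      } else {
        r2 <- suppressWarnings(as.vector(stats::cor(x, G[, vi[open], drop = FALSE]))^2)
        r2[is.na(r2)] <- 0   # zero-variance neighbors
      }
      absorb <- open[r2 >= config$r2_max]
      state[absorb] <- i
    }
    n_absorbed <- c(n_absorbed, sum(state == i))
  }
  index <- cand[index_rows, , drop = FALSE]
  index$n_absorbed <- n_absorbed
  rownames(index) <- NULL
  assigned <- which(state > 0L)
  assignments <- data.frame(snp = cand$snp[assigned],
                            index_snp = cand$snp[state[assigned]],
                            stringsAsFactors = FALSE)
  structure(list(index = index, assignments = assignments, config = config,
                 excluded = excluded),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result> %d index SNPs, %d absorbed, %d excluded (%s mode)\n",
              nrow(x$index), nrow(x$assignments), length(x$excluded),
              x$config$mode))
  invisible(x)
}

#' Fraction of retained SNPs inside a region
#'
#' @param x a `clump_result` (its index SNPs) or a [prs_model()] (its
#'   entries).
#' @param region `c(chr, bp_start, bp_end)`; see [hla_region()].
#' @return fraction in \[0, 1\].
#' @export
hla_fraction <- function(x, region = hla_region()) {
  tab <- if (inherits(x, "clump_result")) x$index
         else if (inherits(x, "prs_model")) x$entries
         else stop("x must be a clump_result or prs_model")
  if (!nrow(tab)) return(0)
  mean(.in_region(tab$chr, tab$bp, region))
}

#' Read gene/pathway intervals from a BED file
#'
#' Standard 0-based half-open BED: columns chrom, start, end and optionally
#' name. A 1-based SNP position `bp` falls in interval `[start, end)` iff
#' `start < bp <= end`.
#'
#' @param path BED file path.
#' @return data.frame `chr`, `start`, `end`, `name`.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3) stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    start <- suppressWarnings(as.numeric(p[2])); end <- suppressWarnings(as.numeric(p[3]))
    if (is.na(start) || is.na(end) || end < start)
      stop(sprintf("malformed BED line %d: bad interval [%s, %s)", i, p[2], p[3]))
    data.frame(chr = p[1], start = start, end = end,
               name = if (length(p) >= 4) p[4] else sprintf("interval_%d", i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$chr <- normalize_chrom(out$chr)
  out
}

#' SNP counts per gene interval
#'
#' Counts how many of the supplied SNPs fall in each BED interval (a SNP may
#' hit several overlapping intervals) and reports the top `k` intervals by
#' count.
#'
#' @param snps data.frame with columns `snp`, `chr`, `bp` (e.g. a
#'   `clump_result$index` or `prs_model$entries`).
#' @param intervals data.frame from [read_bed_intervals()].
#' @param k how many top genes to report (default 5).
#' @return `intervals` with an `n_snps` column, sorted by decreasing count;
#'   the top-`k` subset is attached as attribute `"top"`.
#' @export
gene_enrichment <- function(snps, intervals, k = 5) {
  stopifnot(all(c("chr", "bp") %in% names(snps)),
            all(c("chr", "start", "end") %in% names(intervals)))
  counts <- vapply(seq_len(nrow(intervals)), function(i) {
    sum(snps$chr == intervals$chr[i] &
          snps$bp > intervals$start[i] & snps$bp <= intervals$end[i])
  }, integer(1))
  out <- intervals
  out$n_snps <- counts
  out <- out[order(-out$n_snps, out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top") <- utils::head(out, k)
  out
}
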