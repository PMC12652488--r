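# Individual-level genotype QC: per-variant filters, Hardy-Weinberg exact
# test, kinship-based sample pruning, simple dosage imputation and genetic
# principal components.

# Exact conditional distribution of the heterozygote count given the rare
# allele count r among n diploid genotypes. Returns the probability of every
# attainable het count h in seq(r %% 2, r, 2), via the closed-form
# log-multinomial expression (vectorized over h).
.hwe_het_probs <- function(n, r) {
  h <- seq.int(r %% 2L, r, by = 2L)
  hom_r <- (r - h) / 2
  hom_c <- n - h - hom_r
  logp <- lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
    h * log(2) + lgamma(r + 1) + lgamma(2 * n - r + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  list(h = h, p = p / sum(p))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts whose
#' probability does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative integers).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (!is_count(n_hom_ref) || !is_count(n_het) || !is_count(n_hom_alt))
    stop("genotype counts must be single non-negative integers")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("total genotype count must be positive")
  r <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)  # rare allele count
  d <- .hwe_het_probs(n, r)
  p_obs <- d$p[match(n_het, d$h)]
  min(1, sum(d$p[d$p <= p_obs * (1 + 1e-9)]))
}

# Vectorized HWE p-values from count vectors (used by filter_variants).
.hwe_pvals <- function(n0, n1, n2) {
  mapply(function(a, h, b) hwe_exact_test(a, h, b), n0, n1, n2)
}

#' Per-variant genotype quality-control filters
#'
#' Removes variants failing, in order: genotyping call rate below
#' `call_rate_min`; missing rate above `miss_max`; minor allele frequency
#' below `maf_min`; Hardy-Weinberg exact test p-value below `hwe_p_min`.
#' The call-rate and missing-rate rules are both applied as listed even
#' though the first implies the second at the default settings. HWE is
#' evaluated in controls only when phenotypes are available, otherwise in
#' all samples.
#'
#' @param panel a [genotype_panel()].
#' @param call_rate_min minimum per-variant call rate (default 0.98).
#' @param miss_max maximum per-variant missing rate (default 0.10).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min HWE exact-test p-value threshold (default 0.001).
#' @return the filtered panel, with a per-rule removal count data.frame
#'   attached as attribute `"qc_report"`.
#' @export
filter_variants <- function(panel, call_rate_min = 0.98, miss_max = 0.10,
                            maf_min = 0.01, hwe_p_min = 0.001) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  report <- data.frame(rule = character(0), n_removed = integer(0))
  keep <- rep(TRUE, ncol(dos))
  apply_rule <- function(bad, rule) {
    bad <- bad & keep
    report <<- rbind(report, data.frame(rule = rule, n_removed = sum(bad)))
    keep <<- keep & !bad
  }
  miss_rate <- colMeans(is.na(dos))
  apply_rule(1 - miss_rate < call_rate_min, "call_rate")
  apply_rule(miss_rate > miss_max, "missing_rate")
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  apply_rule(is.na(maf) | maf < maf_min, "maf")

  hwe_rows <- if (any(!is.na(panel$samples$phenotype)) &&
                  any(panel$samples$phenotype %in% 0)) {
    which(panel$samples$phenotype %in% 0)
  } else {
    seq_len(nrow(dos))
  }
  idx <- which(keep)
  if (length(idx)) {
    sub <- round(dos[hwe_rows, idx, drop = FALSE])
    n0 <- colSums(sub == 0, na.rm = TRUE)
    n1 <- colSums(sub == 1, na.rm = TRUE)
    n2 <- colSums(sub == 2, na.rm = TRUE)
    ok <- n0 + n1 + n2 > 0
    hwe_p <- rep(1, length(idx))
    hwe_p[ok] <- .hwe_pvals(n0[ok], n1[ok], n2[ok])
    bad <- rep(FALSE, ncol(dos)); bad[idx] <- hwe_p < hwe_p_min
    apply_rule(bad, "hwe")
  } else {
    report <- rbind(report, data.frame(rule = "hwe", n_removed = 0L))
  }
  if (!any(keep)) stop("no variants survive genotype QC")
  out <- subset_panel(panel, variants = keep)
  attr(out, "qc_report") <- report
  out
}

#' Optional per-sample heterozygosity filter
#'
#' Removes samples whose heterozygosity rate (fraction of non-missing
#' genotypes that are heterozygous) deviates from the cohort mean by more
#' than `n_sd` standard deviations.
#'
#' @param panel a [genotype_panel()].
#' @param n_sd cutoff in standard deviations (default 3).
#' @return the filtered panel with removed iids in attribute `"removed"`.
#' @export
filter_het_outliers <- function(panel, n_sd = 3) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  het <- rowSums(dos == 1, na.rm = TRUE) / rowSums(!is.na(dos))
  bad <- abs(het - mean(het)) > n_sd * stats::sd(het)
  bad[is.na(bad)] <- FALSE
  out <- subset_panel(panel, samples = !bad)
  attr(out, "removed") <- panel$samples$iid[bad]
  out
}

#' Pairwise kinship coefficient
#'
#' Robust moment estimator from shared non-missing genotypes:
#' `phi = (N_het.het - 2 N_opposite.hom) / (N_het(i) + N_het(j))`,
#' where counts are taken over variants observed in both samples. A
#' monozygotic duplicate gives 0.5; unrelated pairs scatter around 0 (and
#' may be negative).
#'
#' @param panel a [genotype_panel()].
#' @param i,j sample iids or row indices.
#' @return kinship estimate (scalar); pairs with fewer than 100 overlapping
#'   variants carry attribute `unreliable = TRUE`.
#' @export
kinship <- function(panel, i, j) {
  stopifnot(inherits(panel, "genotype_panel"))
  ii <- if (is.character(i)) match(i, panel$samples$iid) else i
  jj <- if (is.character(j)) match(j, panel$samples$iid) else j
  if (is.na(ii) || is.na(jj)) stop("unknown sample id")
  gi <- round(panel$dosages[ii, ]); gj <- round(panel$dosages[jj, ])
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("no overlapping non-missing variants between samples")
  gi <- gi[ok]; gj <- gj[ok]
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- sum(gi == 1) + sum(gj == 1)
  if (denom == 0) stop("neither sample has heterozygous genotypes in the overlap")
  phi <- (n_hh - 2 * n_opp) / denom
  if (sum(ok) < 100) attr(phi, "unreliable") <- TRUE
  phi
}

#' Kinship matrix over all sample pairs
#'
#' Matrix formulation of [kinship()] computed with dense cross-products;
#' suitable for a few thousand samples.
#'
#' @param panel a [genotype_panel()].
#' @return symmetric samples-by-samples matrix of kinship estimates
#'   (diagonal set to 0.5).
#' @export
kinship_matrix <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- round(panel$dosages)
  M <- !is.na(g)
  H <- (g == 1) & M; A <- (g == 0) & M; B <- (g == 2) & M
  storage.mode(H) <- "double"; storage.mode(A) <- "double"
  storage.mode(B) <- "double"; storage.mode(M) <- "double"
  n_hh <- tcrossprod(H)
  n_opp <- tcrossprod(A, B); n_opp <- n_opp + t(n_opp)
  denom <- tcrossprod(H, M); denom <- denom + t(denom)
  phi <- (n_hh - 2 * n_opp) / denom
  diag(phi) <- 0.5
  phi
}

#' Remove related samples
#'
#' Greedy pruning: while any pair exceeds `kinship_max`, drop the sample
#' participating in the most such pairs (ties broken by sample order).
#'
#' @param panel a [genotype_panel()].
#' @param kinship_max relatedness threshold (default 0.125, i.e. closer than
#'   third-degree relatives).
#' @return the pruned panel; removed iids in attribute `"removed"`.
#' @export
prune_related <- function(panel, kinship_max = 0.125) {
  stopifnot(inherits(panel, "genotype_panel"))
  phi <- kinship_matrix(panel)
  adj <- !is.na(phi) & phi > kinship_max
  diag(adj) <- FALSE
  removed <- integer(0)
  while (any(adj)) {
    deg <- rowSums(adj)
    drop <- which.max(deg)
    removed <- c(removed, drop)
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  out <- if (length(removed)) subset_panel(panel, samples = -removed) else panel
  attr(out, "removed") <- panel$samples$iid[removed]
  out
}

#' Fill in missing dosages
#'
#' Simple per-variant imputation: each missing entry is replaced by the most
#' frequent observed genotype of that variant (`method = "mode"`, ties going
#' to the smaller dosage) or by the mean observed dosage (`method = "mean"`,
#' which yields fractional dosages).
#'
#' @param panel a [genotype_panel()].
#' @param method `"mode"` (default) or `"mean"`.
#' @return the panel with no missing dosages.
#' @export
impute_dosages <- function(panel, method = c("mode", "mean")) {
  stopifnot(inherits(panel, "genotype_panel"))
  method <- match.arg(method)
  dos <- panel$dosages
  n_obs <- colSums(!is.na(dos))
  if (any(n_obs == 0))
    stop("variant(s) with no observed dosages: ",
         paste(panel$variants$snp[n_obs == 0], collapse = ", "))
  miss_cols <- which(colSums(is.na(dos)) > 0)
  for (jc in miss_cols) {
    x <- dos[, jc]
    fill <- if (method == "mode") {
      counts <- tabulate(round(x[!is.na(x)]) + 1L, nbins = 3L)
      which.max(counts) - 1
    } else {
      mean(x, na.rm = TRUE)
    }
    dos[is.na(x), jc] <- fill
  }
  panel$dosages <- dos
  panel
}

#' Genetic principal components
#'
#' Computes the top `k` principal components of the column-standardized
#' dosage matrix and attaches them to the sample table as covariates
#' `PC1..PCk`. To lighten local LD, variants are first thinned to at most
#' one per `thin_cm` centimorgans when genetic positions are available.
#' Component signs are fixed so that the loading of largest magnitude is
#' positive, making results reproducible up to numerical precision.
#'
#' @param panel an imputed [genotype_panel()] (no missing dosages).
#' @param k number of components (default 20).
#' @param thin_cm minimum genetic distance between variants used for the
#'   decomposition (default 0.5 cM); set `NULL` to use all variants.
#' @return the panel with `PC1..PCk` columns added to `samples`.
#' @export
compute_pcs <- function(panel, k = 20, thin_cm = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$dosages)) stop("panel has missing dosages; impute first")
  v <- panel$variants
  use <- rep(TRUE, nrow(v))
  if (!is.null(thin_cm) && !anyNA(v$cm)) {
    use <- rep(FALSE, nrow(v))
    for (c_ in unique(v$chr)) {
      idx <- which(v$chr == c_)
      idx <- idx[order(v$cm[idx], v$bp[idx])]
      last <- -Inf
      for (i in idx) {
        if (v$cm[i] >= last + thin_cm) { use[i] <- TRUE; last <- v$cm[i] }
      }
    }
  }
  X <- panel$dosages[, use, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (k > min(dim(X)))
    stop(sprintf("k = %d exceeds the panel rank bound min(%d, %d)",
                 k, nrow(X), ncol(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE, rank. = k)
  scores <- pc$x
  for (j in seq_len(ncol(scores))) {   # deterministic sign convention
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  keep <- !grepl("^PC\\d+$", names(panel$samples))
  panel$samples <- cbind(panel$samples[, keep, drop = FALSE],
                         as.data.frame(scores, row.names = NULL))
  panel
}
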