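# Independent reference implementations used to validate the package's
# statistical cores, plus small fixture builders. These deliberately take
# different computational routes from the package code.

# Exact HWE by building the conditional heterozygote distribution through
# the classical probability recurrence (the package uses the closed-form
# log-multinomial expression instead).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  r <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  hs <- seq(r %% 2, r, 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in 2:length(hs)) {
      h <- hs[k - 1]
      hom_r <- (r - h) / 2
      hom_c <- n - h - hom_r
      probs[k] <- probs[k - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# Full HWE p-value vector for every attainable het count at allele count r
# among n genotypes (same recurrence route).
hwe_oracle_all <- function(n, r) {
  hs <- seq(r %% 2, r, 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in 2:length(hs)) {
      h <- hs[k - 1]
      hom_r <- (r - h) / 2
      hom_c <- n - h - hom_r
      probs[k] <- probs[k - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  pv <- vapply(seq_along(hs),
               function(k) min(1, sum(probs[probs <= probs[k] * (1 + 1e-9)])),
               numeric(1))
  list(h = hs, p = pv)
}

# Kendall tau-b by explicit enumeration of all pairs (sign-matrix route).
kendall_oracle <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  S <- sum(sign(outer(x, x, "-")) * sign(outer(y, y, "-"))) / 2
  n0 <- n * (n - 1) / 2
  n1 <- sum(vapply(split(seq_len(n), x), function(ii) length(ii) * (length(ii) - 1) / 2, 1))
  n2 <- sum(vapply(split(seq_len(n), y), function(ii) length(ii) * (length(ii) - 1) / 2, 1))
  list(S = S, tau_b = S / sqrt((n0 - n1) * (n0 - n2)), n1 = n1, n2 = n2)
}

# AUC by the all-pairs definition.
auc_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  cs <- scores[y]; ct <- scores[!y]
  mean(outer(cs, ct, ">") + 0.5 * outer(cs, ct, "=="))
}

# Exhaustive greedy clumping reference: recomputes the candidate ordering
# and every eligibility condition from scratch at each step, with direct
# per-pair Pearson correlations.
clump_oracle <- function(ss, panel, config) {
  cand <- as.data.frame(ss)
  if (!is.null(config$exclude_region)) {
    r <- config$exclude_region
    cand <- cand[!(cand$chr == r[1] & cand$bp >= r[2] & cand$bp <= r[3]), ]
  }
  pos <- if (config$mode == "genetic") cand$cm else cand$bp
  halfw <- if (config$mode == "genetic") config$window_cm else config$window_kb * 1000
  names(pos) <- cand$snp
  unassigned <- cand$snp
  index <- character(0)
  assignments <- data.frame(snp = character(0), index_snp = character(0),
                            stringsAsFactors = FALSE)
  while (length(unassigned)) {
    sub <- cand[cand$snp %in% unassigned, ]
    sub <- sub[order(sub$p, sub$bp, sub$snp), ]
    best <- sub$snp[1]
    index <- c(index, best)
    unassigned <- setdiff(unassigned, best)
    gi <- panel$dosages[, best]
    absorbed <- character(0)
    for (s in unassigned) {
      same_chr <- cand$chr[cand$snp == s] == cand$chr[cand$snp == best]
      close <- abs(pos[[s]] - pos[[best]]) <= halfw
      gj <- panel$dosages[, s]
      r2 <- if (sd(gi) == 0 || sd(gj) == 0) 0 else cor(gi, gj)^2
      if (same_chr && close && r2 >= config$r2_max) absorbed <- c(absorbed, s)
    }
    if (length(absorbed))
      assignments <- rbind(assignments,
                           data.frame(snp = absorbed, index_snp = best,
                                      stringsAsFactors = FALSE))
    unassigned <- setdiff(unassigned, absorbed)
  }
  list(index = index, assignments = assignments)
}

# Panel of independent SNPs at Hardy-Weinberg proportions.
rand_panel <- function(n, m, seed = 1, maf = NULL, chr = NULL, miss_rate = 0,
                       pheno_frac = NA) {
  set.seed(seed)
  maf <- maf %||% runif(m, 0.1, 0.5)
  if (length(maf) == 1) maf <- rep(maf, m)
  dos <- vapply(seq_len(m), function(j) rbinom(n, 2, maf[j]), numeric(n))
  if (miss_rate > 0) dos[matrix(runif(n * m) < miss_rate, n)] <- NA
  chr <- chr %||% rep(1L, m)
  if (length(chr) == 1) chr <- rep(chr, m)
  bases <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  alleles <- t(vapply(seq_len(m), function(j) bases[[1 + (j %% 4)]], character(2)))
  variants <- data.frame(snp = sprintf("s%03d", seq_len(m)), chr = chr,
                         bp = seq_len(m) * 1e5, a1 = alleles[, 1],
                         a2 = alleles[, 2], cm = seq_len(m) * 0.1,
                         stringsAsFactors = FALSE)
  pheno <- if (is.na(pheno_frac)) rep(NA_real_, n) else rbinom(n, 1, pheno_frac)
  samples <- data.frame(iid = sprintf("i%03d", seq_len(n)),
                        sex = rep(c("male", "female"), length.out = n),
                        phenotype = pheno, stringsAsFactors = FALSE)
  genotype_panel(dos, variants, samples)
}

# Harmonized-sumstats table aligned to a panel, with supplied or random
# p-values/betas (skips the read/QC path so clumping can be driven directly).
fake_harmonized <- function(panel, p = NULL, beta = NULL, seed = 1) {
  set.seed(seed)
  v <- panel$variants
  m <- nrow(v)
  out <- data.frame(snp = v$snp, chr = v$chr, bp = v$bp, cm = v$cm,
                    a1 = v$a1, a2 = v$a2,
                    beta = beta %||% rnorm(m, 0, 0.1),
                    se = rep(0.05, m),
                    p = p %||% runif(m), n = rep(1000, m),
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_sumstats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
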