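# Ordinal PRS-metabolite association: KNN completion of the metabolite
# panel, per-sex quantile binning of adjusted scores, Kendall tau-b with tie
# corrections, sex-distribution comparison and the pathway-vs-full
# proportion-of-correlation-explained statistic.

#' Construct a metabolite panel
#'
#' @param values numeric samples-by-metabolites matrix (may contain `NA`);
#'   row names are sample iids, column names metabolite names.
#' @param sex per-sample sex ("male"/"female"), recycled against rows.
#' @return a `metabolite_panel` (list with `values`, `sex`, `iid`).
#' @export
metabolite_panel <- function(values, sex) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("metabolite columns must be named")
  if (anyDuplicated(colnames(values))) stop("duplicate metabolite names")
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  sex <- rep_len(as.character(sex), nrow(values))
  if (anyNA(sex)) stop("sex must be non-missing for every retained sample")
  structure(list(values = values, sex = sex, iid = rownames(values)),
            class = "metabolite_panel")
}

#' K-nearest-neighbour completion of a metabolite panel
#'
#' Each missing cell is replaced by the mean of that metabolite over the `k`
#' nearest samples (among those observing it). Distances are Euclidean on
#' per-metabolite standardized columns, averaged over the columns the two
#' samples jointly observe. Samples with every metabolite missing are
#' dropped with a warning; observed cells are untouched.
#'
#' @param panel a [metabolite_panel()].
#' @param k neighbourhood size (default 10); every metabolite must have at
#'   least `k` observed values.
#' @return the completed `metabolite_panel`.
#' @export
knn_impute <- function(panel, k = 10) {
  stopifnot(inherits(panel, "metabolite_panel"), k >= 1)
  X <- panel$values
  all_miss <- rowSums(!is.na(X)) == 0
  if (any(all_miss)) {
    warning(sprintf("dropping %d sample(s) with all metabolites missing", sum(all_miss)))
    X <- X[!all_miss, , drop = FALSE]
    panel$sex <- panel$sex[!all_miss]
    panel$iid <- panel$iid[!all_miss]
  }
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < k))
    stop("metabolite(s) with fewer than k observed values: ",
         paste(colnames(X)[n_obs < k], collapse = ", "))
  if (!anyNA(X)) { panel$values <- X; return(panel) }
  mu <- colMeans(X, na.rm = TRUE)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds) | sds == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  out <- X
  for (i in which(rowSums(is.na(X)) > 0)) {
    zi <- Z[i, ]
    obs_i <- !is.na(zi)
    # mean squared difference over jointly observed standardized columns
    D2 <- sweep(Z[, obs_i, drop = FALSE], 2, zi[obs_i])^2
    shared <- rowSums(!is.na(D2))
    d <- sqrt(rowMeans(D2, na.rm = TRUE))
    d[shared == 0] <- Inf
    d[i] <- Inf
    for (jm in which(is.na(X[i, ]))) {
      cand <- which(!is.na(X[, jm]) & is.finite(d))
      cand <- cand[order(d[cand], cand)]   # stable tie-break by row order
      nb <- utils::head(cand, k)
      out[i, jm] <- mean(X[nb, jm])
    }
  }
  panel$values <- out
  panel
}

#' Five-level per-sex PRS categories
#'
#' Within each sex, adjusted scores are binned by their empirical percentile
#' rank `(rank - 1) / n` into bottom 10% (`< 10th` percentile), low 30%
#' (`[10th, 40th)`), middle 20% (`[40th, 60th)`), high 30% (`[60th, 90th)`)
#' and top 10% (`>= 90th` percentile). For `n` divisible by 10 with distinct
#' scores the counts are exactly (10, 30, 20, 30, 10)% of `n`; being
#' rank-based, the categories are invariant under any strictly monotone
#' transformation of the scores.
#'
#' @param scores numeric adjusted scores.
#' @param sex per-sample sex, same length as `scores`.
#' @return ordered factor with levels `bottom10 < low30 < mid20 < high30 <
#'   top10`.
#' @export
categorize <- function(scores, sex) {
  stopifnot(length(scores) == length(sex))
  lv <- c("bottom10", "low30", "mid20", "high30", "top10")
  out <- rep(NA_character_, length(scores))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    if (length(idx) < 10)
      stop(sprintf("sex '%s' has fewer than 10 samples", s))
    x <- scores[idx]
    if (length(unique(x)) == 1)
      stop("degenerate score distribution: all scores identical within a sex")
    frac <- (rank(x, ties.method = "average") - 1) / length(x)
    out[idx] <- lv[findInterval(frac, c(0, 0.1, 0.4, 0.6, 0.9))]
  }
  factor(out, levels = lv, ordered = TRUE)
}

# (C - D) and tie sums from an r x c contingency table. Each pair is counted
# once at its "later" member: C = sum_ij n_ij * N(k<i, l<j),
# D = sum_ij n_ij * N(k<i, l>j), both read off a zero-padded double
# cumulative-sum matrix.
.kendall_counts <- function(tab) {
  tab <- unclass(as.matrix(tab))
  r <- nrow(tab); c_ <- ncol(tab)
  P <- matrix(0, r + 1, c_ + 1)
  P[-1, -1] <- tab
  P <- apply(P, 2, cumsum)
  P <- t(apply(P, 1, cumsum))            # P[i+1, j+1] = sum_{k<=i, l<=j}
  A <- P[1:r, 1:c_, drop = FALSE]                        # k < i, l < j
  B <- matrix(P[1:r, c_ + 1], r, c_) - P[1:r, 2:(c_ + 1), drop = FALSE]  # k < i, l > j
  ti <- rowSums(tab); uj <- colSums(tab)
  list(S = sum(tab * A) - sum(tab * B), n = sum(tab),
       n1 = sum(ti * (ti - 1) / 2), n2 = sum(uj * (uj - 1) / 2),
       ti = ti, uj = uj)
}

#' Kendall's tau-b with tie-corrected significance
#'
#' Tau-b = `(C - D) / sqrt((n0 - n1)(n0 - n2))` where `n0 = n(n-1)/2` and
#' `n1`, `n2` are the tie sums of `x` and `y`. The p-value uses the normal
#' approximation with the tie-corrected null variance of `C - D`, and the
#' 95% confidence interval is built from the corresponding asymptotic
#' standard error of tau-b.
#'
#' @param x ordinal values (e.g. PRS categories); at least 2 distinct levels.
#' @param y numeric values.
#' @param conf confidence level (default 0.95).
#' @return list with `tau_b`, `p`, `ci` (length-2), `n`.
#' @export
kendall_tau_b <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("kendall_tau_b requires n >= 10")
  xr <- as.integer(factor(rank(as.numeric(x))))
  if (length(unique(xr)) < 2) stop("x is constant; tau-b undefined")
  tab <- table(xr, rank(y))
  k <- .kendall_counts(tab)
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - k$n1) * (n0 - k$n2))
  if (denom == 0) stop("degenerate tie structure; tau-b undefined")
  tau <- k$S / denom
  # tie-corrected null variance of S = C - D (as in the classical normal
  # approximation for Kendall's statistic with ties)
  ti <- k$ti; uj <- k$uj
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5))
  vu <- sum(uj * (uj - 1) * (2 * uj + 5))
  v1 <- sum(ti * (ti - 1)) * sum(uj * (uj - 1)) / (2 * n * (n - 1))
  v2 <- sum(ti * (ti - 1) * (ti - 2)) * sum(uj * (uj - 1) * (uj - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- k$S / sqrt(var_s)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  se_tau <- sqrt(var_s) / denom
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(tau_b = tau, p = p, ci = c(tau - q * se_tau, tau + q * se_tau), n = n)
}

#' Per-metabolite, per-sex association between PRS categories and metabolites
#'
#' Runs [kendall_tau_b()] for every metabolite within each sex separately
#' and appends a Benjamini-Hochberg q-value computed across metabolites
#' within each sex.
#'
#' @param categories ordered factor from [categorize()], named by iid (or
#'   aligned with the metabolite panel rows).
#' @param metabolites a completed [metabolite_panel()] (no missing values).
#' @param score_kind label recorded per row (`"full"` or `"pathway"`).
#' @return an `association_table` data.frame with columns `metabolite`,
#'   `sex`, `score_kind`, `tau_b`, `p`, `ci_low`, `ci_high`, `n`, `q`.
#' @export
associate <- function(categories, metabolites, score_kind = "full") {
  stopifnot(inherits(metabolites, "metabolite_panel"))
  ids <- names(categories) %||% metabolites$iid
  m <- match(metabolites$iid, ids)
  if (all(is.na(m))) stop("no shared samples between categories and metabolites")
  keep <- !is.na(m)
  X <- metabolites$values[keep, , drop = FALSE]
  sex <- metabolites$sex[keep]
  cats <- categories[m[keep]]
  rows <- list()
  for (s in sort(unique(sex))) {
    idx <- which(sex == s)
    for (met in colnames(X)) {
      kt <- kendall_tau_b(cats[idx], X[idx, met])
      rows[[length(rows) + 1L]] <-
        data.frame(metabolite = met, sex = s, score_kind = score_kind,
                   tau_b = kt$tau_b, p = kt$p, ci_low = kt$ci[1],
                   ci_high = kt$ci[2], n = kt$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::ave(out$p, out$sex, FUN = function(p) stats::p.adjust(p, "BH"))
  class(out) <- c("association_table", "data.frame")
  out
}

#' Compare score distributions between sexes
#'
#' Two-sample Kolmogorov-Smirnov test of the male vs female adjusted-score
#' distributions.
#'
#' @param scores numeric adjusted scores.
#' @param sex per-sample sex.
#' @return list with `statistic` (KS D) and `p` (asymptotic).
#' @export
sex_distribution_test <- function(scores, sex) {
  xm <- scores[sex == "male"]; xf <- scores[sex == "female"]
  if (length(xm) < 10 || length(xf) < 10)
    stop("both sexes must be present with n >= 10")
  kt <- suppressWarnings(stats::ks.test(xm, xf))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Proportion of the full-score correlation explained by a pathway score
#'
#' Aligns the full-score and pathway-score association tables on
#' (metabolite, sex) and fits the no-intercept least-squares slope of
#' pathway tau-b on full tau-b across the aligned pairs; a slope of 1 means
#' the pathway score reproduces the full correlations, and the slope may
#' exceed 1. The confidence interval is a percentile bootstrap over pairs.
#'
#' @param full,pathway `association_table`s from [associate()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return list with `slope`, `ci` (length-2), `n_pairs`.
#' @export
proportion_explained <- function(full, pathway, n_boot = 1000, seed = 1,
                                 conf = 0.95) {
  key <- function(t) paste(t$metabolite, t$sex)
  m <- match(key(full), key(pathway))
  if (anyNA(m)) stop("tables do not align on (metabolite, sex)")
  f <- full$tau_b
  g <- pathway$tau_b[m]
  if (length(f) < 5) stop("need at least 5 aligned (metabolite, sex) pairs")
  if (all(f == 0)) stop("all full-score tau-b are zero; slope undefined")
  slope <- sum(f * g) / sum(f^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(f), replace = TRUE)
      ss <- sum(f[idx]^2)
      if (ss == 0) return(NA_real_)
      sum(f[idx] * g[idx]) / ss
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(slope = slope, ci = ci, n_pairs = length(f))
}
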