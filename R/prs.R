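# Polygenic risk scores: model construction at a p-value threshold,
# additive scoring, covariate adjustment, train/test splitting and
# AUC-driven threshold selection; pathway-restricted models.

#' The p-value threshold grid used for model selection
#'
#' @return numeric vector `1e-8, 5e-8, 1e-5, 5e-5, 0.001, 0.01, 0.05, 0.1,
#'   0.2, 0.5`.
#' @export
threshold_grid <- function() {
  c(1e-8, 5e-8, 1e-5, 5e-5, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5)
}

#' Build a PRS model from clumped SNPs at a p-value threshold
#'
#' @param clumped a `clump_result` from [clump()].
#' @param threshold p-value cutoff: index SNPs with `p <= threshold` enter
#'   the model with their harmonized weights.
#' @return a `prs_model`: list with `entries` (data.frame `snp`, `chr`,
#'   `bp`, `cm`, `a1`, `a2`, `beta`, `p`), `threshold` and `provenance`.
#' @export
build_model <- function(clumped, threshold) {
  stopifnot(inherits(clumped, "clump_result"), threshold > 0, threshold <= 1)
  keep <- clumped$index$p <= threshold
  if (!any(keep))
    stop(sprintf("no index SNPs with p <= %g", threshold))
  entries <- clumped$index[keep, c("snp", "chr", "bp", "cm", "a1", "a2",
                                   "beta", "p"), drop = FALSE]
  rownames(entries) <- NULL
  cfg <- clumped$config
  structure(list(entries = entries, threshold = threshold,
                 provenance = list(mode = cfg$mode,
                                   window = if (cfg$mode == "genetic")
                                     cfg$window_cm else cfg$window_kb,
                                   r2_max = cfg$r2_max,
                                   hla_excluded = !is.null(cfg$exclude_region),
                                   pathway = NULL)),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d SNPs at p <= %g (%s mode%s)\n",
              nrow(x$entries), x$threshold, x$provenance$mode,
              if (isTRUE(x$provenance$hla_excluded)) ", HLA excluded" else ""))
  invisible(x)
}

#' Score samples with a PRS model
#'
#' Raw additive score `S_i = sum_j beta_j G_ij`. Panel variants whose allele
#' pair is swapped relative to the model are reconciled by negating the
#' weight (exactly as in [harmonize()]), so scores are invariant to
#' allele-swapped, sign-flipped model copies. Model SNPs absent from the
#' panel (or with mismatched alleles) are dropped with a warning, and fewer
#' than 50% usable SNPs is an error.
#'
#' @param panel an imputed [genotype_panel()].
#' @param model a [prs_model()] (or [build_model()] output).
#' @param average divide the score by `2 * n_snps` (average per allele);
#'   default `FALSE` reports the plain weighted sum.
#' @return named numeric vector of per-sample scores. Dropped snp ids are
#'   attached as attribute `"dropped"` when any.
#' @export
score_prs <- function(panel, model, average = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(model, "prs_model"))
  e <- model$entries
  vi <- match(e$snp, panel$variants$snp)
  pv <- panel$variants[ifelse(is.na(vi), 1L, vi), , drop = FALSE]
  same <- !is.na(vi) & e$a1 == pv$a1 & e$a2 == pv$a2
  swap <- !is.na(vi) & e$a1 == pv$a2 & e$a2 == pv$a1
  usable <- same | swap
  if (!all(usable)) {
    warning(sprintf("%d model SNP(s) missing from panel or allele-mismatched; dropped",
                    sum(!usable)))
    if (mean(usable) < 0.5)
      stop("fewer than 50% of model SNPs are present in the panel")
  }
  G <- panel$dosages[, vi[usable], drop = FALSE]
  b <- e$beta[usable]
  sw <- swap[usable]
  # swapped orientation is reconciled as in harmonize(): negate the weight.
  # (The per-SNP constant 2*beta from the dosage complement is dropped; it
  # shifts every sample equally and scoring is therefore exactly invariant
  # to allele-swapped, sign-flipped model copies.)
  scores <- as.vector(G %*% ifelse(sw, -b, b))
  if (average) scores <- scores / (2 * sum(usable))
  names(scores) <- panel$samples$iid
  if (any(!usable)) attr(scores, "dropped") <- e$snp[!usable]
  scores
}

#' Covariate-adjust PRS scores by residualization
#'
#' Residual of the least-squares regression of the raw score on the
#' covariates plus an intercept; adjusted scores have mean zero. Constant
#' (zero-variance) covariate columns are dropped before fitting;
#' rank-deficient covariates after that are an error.
#'
#' @param scores numeric vector of raw scores.
#' @param covariates data.frame or matrix of covariates (e.g. top principal
#'   components, sex indicator), one row per sample.
#' @return numeric vector of adjusted scores (names preserved).
#' @export
adjust_score <- function(scores, covariates) {
  X <- as.matrix(covariates)
  if (nrow(X) != length(scores)) stop("covariates and scores disagree in length")
  if (any(is.na(X))) stop("covariates contain missing values")
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, scores)
  if (fit$rank < ncol(Xi)) stop("rank-deficient covariate matrix")
  res <- fit$residuals
  names(res) <- names(scores)
  res
}

#' Stratified train/test split
#'
#' Random split stratified by phenotype (and additionally by sex when
#' `by_sex = TRUE`); each stratum contributes `round(ratio * n)` samples to
#' the training set, so the case fraction is preserved to within one sample
#' per stratum. Reproducible under a fixed seed.
#'
#' @param samples sample data.frame with `phenotype` (and `sex`).
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @param by_sex also stratify by sex (default `FALSE`).
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   union = all rows with non-missing phenotype).
#' @export
split_train_test <- function(samples, ratio = 0.8, seed = 1, by_sex = FALSE) {
  stopifnot(ratio > 0, ratio < 1)
  ok <- which(!is.na(samples$phenotype))
  strata <- samples$phenotype[ok]
  if (by_sex) strata <- paste(strata, samples$sex[ok])
  tab <- table(strata)
  if (length(tab) < 2 || length(unique(samples$phenotype[ok])) < 2)
    stop("both cases and controls are required in the split")
  if (any(tab < 5) || length(ok) < 10)
    stop("stratum too small for a train/test split")
  train <- with_seed(seed, {
    unlist(lapply(split(ok, strata), function(idx) {
      n_tr <- max(1L, min(length(idx) - 1L, round(ratio * length(idx))))
      sort(sample(idx, n_tr))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = sort(setdiff(ok, train)))
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random case scores above a random
#' control, with ties counted one-half.
#'
#' @param scores numeric scores.
#' @param labels case/control labels (1/0, logical, or "case"/"control").
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "case"
  y <- as.logical(labels)
  if (anyNA(y) || anyNA(scores)) stop("scores/labels contain missing values")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the optimal p-value threshold by held-out AUC
#'
#' For each threshold in the grid, builds the PRS model from the clumped
#' index SNPs, scores the panel, residualizes on the covariates, and
#' computes the AUC on the held-out test split. Thresholds admitting no SNPs
#' are skipped. The chosen threshold maximizes test AUC, with ties broken
#' toward the smaller (more stringent) threshold.
#'
#' @param clumped a `clump_result`.
#' @param panel an imputed, PC-annotated target [genotype_panel()] with
#'   case/control phenotypes.
#' @param grid p-value thresholds (default [threshold_grid()]).
#' @param ratio training fraction for the split (default 0.8).
#' @param seed split seed.
#' @param covariates adjustment covariates; default uses the panel's
#'   `PC1..PCk` columns plus a sex indicator.
#' @param split optional precomputed split (list `train`/`test`) so that
#'   several methods can share identical train/test samples.
#' @param evaluator `"residual"` (AUC of the covariate-residualized score,
#'   default) or `"logistic"` (AUC of a logistic model with score and
#'   covariates as predictors, fit on the training split).
#' @return a `threshold_selection`: list with `selection` (data.frame
#'   `threshold`, `n_snps`, `auc_train`, `auc_test`), `chosen`, the winning
#'   `model`, per-sample `scores` and `adjusted` scores, the `split`,
#'   `seed` and `ratio`.
#' @export
select_threshold <- function(clumped, panel, grid = threshold_grid(),
                             ratio = 0.8, seed = 1, covariates = NULL,
                             split = NULL,
                             evaluator = c("residual", "logistic")) {
  stopifnot(inherits(clumped, "clump_result"), inherits(panel, "genotype_panel"))
  evaluator <- match.arg(evaluator)
  if (is.null(covariates)) {
    pcs <- grep("^PC\\d+$", names(panel$samples), value = TRUE)
    covariates <- panel$samples[, pcs, drop = FALSE]
    covariates$sex_male <- as.numeric(panel$samples$sex == "male")
  }
  if (is.null(split)) split <- split_train_test(panel$samples, ratio, seed)
  y <- panel$samples$phenotype
  grid <- sort(grid)
  rows <- list(); kept <- list()
  for (thr in grid) {
    model <- tryCatch(build_model(clumped, thr), error = function(e) NULL)
    if (is.null(model)) next
    raw <- score_prs(panel, model)
    adj <- adjust_score(raw, covariates)
    if (evaluator == "logistic") {
      dat <- data.frame(y = y, s = raw, covariates)
      fit <- stats::glm(y ~ ., data = dat[split$train, , drop = FALSE],
                        family = stats::binomial())
      pred <- stats::predict(fit, newdata = dat, type = "link")
      auc_tr <- evaluate_auc(pred[split$train], y[split$train])
      auc_te <- evaluate_auc(pred[split$test], y[split$test])
    } else {
      auc_tr <- evaluate_auc(adj[split$train], y[split$train])
      auc_te <- evaluate_auc(adj[split$test], y[split$test])
    }
    rows[[length(rows) + 1L]] <- data.frame(threshold = thr,
                                            n_snps = nrow(model$entries),
                                            auc_train = auc_tr,
                                            auc_test = auc_te)
    kept[[length(kept) + 1L]] <- list(model = model, raw = raw, adj = adj)
  }
  if (!length(rows)) stop("every threshold in the grid admitted zero SNPs")
  selection <- do.call(rbind, rows)
  best <- which.max(selection$auc_test)  # grid sorted ascending: first max wins
  structure(list(selection = selection, chosen = selection$threshold[best],
                 model = kept[[best]]$model, scores = kept[[best]]$raw,
                 adjusted = kept[[best]]$adj, split = split, seed = seed,
                 ratio = ratio, evaluator = evaluator),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> chosen p <= %g (test AUC %.3f, %d SNPs)\n",
              x$chosen, max(x$selection$auc_test),
              x$selection$n_snps[which.max(x$selection$auc_test)]))
  print(x$selection, row.names = FALSE)
  invisible(x)
}

#' Restrict a PRS model to pathway gene regions
#'
#' Keeps the model SNPs falling in any of the supplied BED intervals
#' (0-based half-open; a 1-based bp is inside `[start, end)` iff
#' `start < bp <= end`).
#'
#' @param model a [prs_model()].
#' @param intervals data.frame from [read_bed_intervals()].
#' @param name pathway label recorded in the model provenance.
#' @return the restricted `prs_model`.
#' @export
pathway_subset <- function(model, intervals, name = "pathway") {
  stopifnot(inherits(model, "prs_model"),
            all(c("chr", "start", "end") %in% names(intervals)))
  e <- model$entries
  hit <- vapply(seq_len(nrow(e)), function(i) {
    any(intervals$chr == e$chr[i] &
          e$bp[i] > intervals$start & e$bp[i] <= intervals$end)
  }, logical(1))
  if (!any(hit))
    stop(sprintf("no model SNPs fall in pathway '%s'", name))
  model$entries <- e[hit, , drop = FALSE]
  rownames(model$entries) <- NULL
  model$provenance$pathway <- name
  model
}
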