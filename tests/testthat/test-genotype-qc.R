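test_that("variant filters remove planted failures and are idempotent", {
  set.seed(12)
  panel <- rand_panel(200, 50, seed = 12, maf = 0.3)
  dos <- panel$dosages
  dos[sample(200, 30), 1] <- NA                 # 15% missing -> call rate + miss
  dos[, 2] <- 0                                 # monomorphic -> MAF
  dos[, 3] <- rbinom(200, 2, 0.005)             # rare -> MAF
  dos[, 4] <- rep(c(0, 2), each = 100)          # no hets -> HWE
  dos[sample(200, 6), 5] <- NA                  # 3% missing -> call rate only
  panel$dosages <- dos
  out <- filter_variants(panel)
  expect_equal(ncol(out$dosages), 45)
  expect_false(any(c("s001", "s002", "s003", "s004", "s005") %in% out$variants$snp))
  rep_ <- attr(out, "qc_report")
  expect_equal(sum(rep_$n_removed), 5)
  again <- filter_variants(out)
  expect_equal(again$variants$snp, out$variants$snp)
  expect_equal(sum(attr(again, "qc_report")$n_removed), 0)
})

test_that("HWE is evaluated in controls when phenotypes exist", {
  set.seed(13)
  n <- 300
  dos <- cbind(rbinom(n, 2, 0.4))
  pheno <- rep(c(0, 1), each = n / 2)
  dos[pheno == 1] <- 1                           # cases all het: HWE-violating
  panel <- genotype_panel(
    dos,
    data.frame(snp = "v1", chr = 1, bp = 100, a1 = "A", a2 = "G"),
    data.frame(iid = sprintf("i%03d", 1:n), sex = "male", phenotype = pheno))
  out <- filter_variants(panel, maf_min = 0.01)  # controls alone are in HWE
  expect_equal(ncol(out$dosages), 1)
})

test_that("HWE exact test matches enumeration and is symmetric", {
  expect_equal(hwe_exact_test(20, 0, 0), 1)
  expect_equal(hwe_exact_test(14, 57, 50), hwe_oracle(14, 57, 50))
  set.seed(14)
  for (i in 1:100) {
    cnt <- sample(0:60, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    p1 <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    expect_equal(p1, hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
    expect_equal(p1, hwe_exact_test(cnt[3], cnt[2], cnt[1]))
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("kinship is 0.5 for duplicates, negative for opposite homozygotes, ~0 for unrelateds", {
  panel <- rand_panel(10, 300, seed = 15, maf = 0.4)
  panel$dosages[2, ] <- panel$dosages[1, ]       # duplicate pair
  expect_equal(kinship(panel, 1, 2), 0.5, ignore_attr = TRUE)

  dos <- rbind(c(0, 0, 2, 2, 1), c(2, 2, 0, 0, 1))
  p2 <- genotype_panel(
    dos, data.frame(snp = paste0("v", 1:5), chr = 1, bp = 1:5 * 100,
                    a1 = "A", a2 = "G"),
    data.frame(iid = c("a", "b"), sex = "male", phenotype = NA))
  expect_lt(suppressWarnings(kinship(p2, "a", "b")), 0)

  big <- rand_panel(100, 5000, seed = 16, maf = runif(5000, 0.1, 0.5))
  phi <- kinship_matrix(big)
  pairs <- phi[upper.tri(phi)][1:50]
  expect_lt(abs(mean(pairs)), 0.02)
  # matrix agrees with the pairwise definition
  expect_equal(phi[3, 7], kinship(big, 3, 7), ignore_attr = TRUE)
})

test_that("relatedness pruning removes duplicates and breaks up cliques", {
  panel <- rand_panel(12, 400, seed = 17, maf = 0.4)
  panel$dosages[2, ] <- panel$dosages[1, ]
  out <- prune_related(panel)
  expect_equal(nrow(out$dosages), 11)
  expect_length(attr(out, "removed"), 1)

  clean <- rand_panel(10, 400, seed = 18, maf = 0.4)
  same <- prune_related(clean)
  expect_equal(nrow(same$dosages), 10)

  fam <- rand_panel(9, 500, seed = 19, maf = 0.4)
  fam$dosages[2, ] <- fam$dosages[1, ]
  fam$dosages[3, ] <- fam$dosages[1, ]           # 3-clique of duplicates
  pruned <- prune_related(fam)
  expect_equal(nrow(pruned$dosages), 7)
  phi <- kinship_matrix(pruned)
  diag(phi) <- 0
  expect_true(all(phi <= 0.125, na.rm = TRUE))   # post-condition
})

test_that("dosage imputation fills by mode or mean and leaves observed cells", {
  dos <- matrix(c(0, 0, 0, 1, NA,
                  0, 2, NA, NA, 2,
                  1, 1, 1, 1, 1), nrow = 5)
  panel <- genotype_panel(
    dos, data.frame(snp = c("v1", "v2", "v3"), chr = 1, bp = 1:3 * 100,
                    a1 = "A", a2 = "G"),
    data.frame(iid = letters[1:5], sex = "male", phenotype = NA))
  mode_p <- impute_dosages(panel)
  expect_equal(mode_p$dosages[5, 1], 0)          # mode of {0,0,0,1}
  expect_equal(unname(mode_p$dosages[3:4, 2]), c(2, 2))  # mode of {0,2,2} is 2
  expect_equal(mode_p$dosages[, 3], panel$dosages[, 3])
  mean_p <- impute_dosages(panel, method = "mean")
  expect_equal(mean_p$dosages[3, 2], mean(c(0, 2, 2)))
  full <- impute_dosages(mode_p)
  expect_equal(full$dosages, mode_p$dosages)     # identity when complete
})

test_that("principal components are orthogonal and match a dense eigen-oracle", {
  panel <- rand_panel(20, 30, seed = 21, maf = 0.4)
  out <- compute_pcs(panel, k = 5, thin_cm = NULL)
  pcs <- as.matrix(out$samples[, paste0("PC", 1:5)])
  gram <- crossprod(pcs)
  expect_equal(gram[upper.tri(gram)], rep(0, 10), tolerance = 1e-8)
  # eigen-oracle on the standardized matrix
  X <- scale(panel$dosages)
  ei <- eigen(stats::cov(X), symmetric = TRUE)
  oracle <- X %*% ei$vectors[, 1:5]
  for (j in 1:5)
    expect_equal(abs(stats::cor(pcs[, j], oracle[, j])), 1, tolerance = 1e-6)
  expect_error(compute_pcs(panel, k = 25), "exceeds")
})

test_that("a rank-1 panel concentrates variance in PC1", {
  set.seed(22)
  base <- rbinom(40, 2, 0.5)
  dos <- matrix(rep(base, 6), ncol = 6)
  panel <- genotype_panel(
    dos, data.frame(snp = paste0("v", 1:6), chr = 1, bp = 1:6 * 100,
                    a1 = "A", a2 = "G"),
    data.frame(iid = sprintf("i%02d", 1:40), sex = "male", phenotype = NA))
  out <- compute_pcs(panel, k = 2, thin_cm = NULL)
  v1 <- var(out$samples$PC1); v2 <- var(out$samples$PC2)
  expect_gt(v1 / (v1 + v2), 0.999)
})

test_that("sample heterozygosity outliers can be screened", {
  panel <- rand_panel(60, 300, seed = 23, maf = 0.3)
  panel$dosages[1, ] <- 1                        # everything heterozygous
  out <- filter_het_outliers(panel)
  expect_equal(attr(out, "removed"), "i001")
})
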