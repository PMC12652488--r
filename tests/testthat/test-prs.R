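clumped_fixture <- function() {
  panel <- rand_panel(60, 12, seed = 50)
  hw <- fake_harmonized(panel, p = c(1e-9, 1e-6, 1e-3, rep(0.3, 9)), seed = 50)
  list(panel = panel,
       clumped = clump(hw, panel, clump_config(window_cm = 0.01, r2_max = 0.99)))
}

test_that("model construction keeps exactly the index SNPs passing the threshold", {
  fx <- clumped_fixture()
  expect_equal(nrow(build_model(fx$clumped, 0.5)$entries), 12)
  expect_equal(nrow(build_model(fx$clumped, 1e-5)$entries), 2)
  expect_error(build_model(fx$clumped, 1e-12), "no index SNPs")
})

test_that("scoring is additive, scale-equivariant and flip-invariant", {
  fx <- clumped_fixture()
  model <- build_model(fx$clumped, 0.5)
  s <- score_prs(fx$panel, model)

  zero <- model; zero$entries$beta <- 0
  expect_equal(unname(score_prs(fx$panel, zero)), rep(0, 60))

  one <- model; one$entries <- model$entries[1, , drop = FALSE]
  one$entries$beta <- 0.5
  g <- fx$panel$dosages[, one$entries$snp]
  expect_equal(unname(score_prs(fx$panel, one)), unname(0.5 * g))

  flipped <- model
  flipped$entries$a1 <- model$entries$a2
  flipped$entries$a2 <- model$entries$a1
  flipped$entries$beta <- -model$entries$beta
  expect_equal(score_prs(fx$panel, flipped), s)

  a <- model; a$entries <- model$entries[1:5, ]
  b <- model; b$entries <- model$entries[6:12, ]
  expect_equal(score_prs(fx$panel, a) + score_prs(fx$panel, b), s)

  dbl <- model; dbl$entries$beta <- 2 * model$entries$beta
  expect_equal(score_prs(fx$panel, dbl), 2 * s)
  y <- rbinom(60, 1, 0.5); y[1] <- 0; y[2] <- 1
  expect_equal(evaluate_auc(2 * s, y), evaluate_auc(s, y))
})

test_that("missing model SNPs warn, and scoring fails below 50% coverage", {
  fx <- clumped_fixture()
  model <- build_model(fx$clumped, 0.5)
  small <- subset_panel(fx$panel, variants = fx$panel$variants$snp[1:11])
  expect_warning(s <- score_prs(small, model), "dropped")
  expect_equal(attr(s, "dropped"), "s012")
  tiny <- subset_panel(fx$panel, variants = fx$panel$variants$snp[1:5])
  expect_error(suppressWarnings(score_prs(tiny, model)), "50%")
})

test_that("adjustment residualizes, centers and orthogonalizes against PCs", {
  set.seed(51)
  n <- 100
  pcs <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  s <- 2 + pcs %*% c(1, -2, 0.5) + rnorm(n)
  adj <- adjust_score(as.vector(s), pcs)
  expect_equal(mean(adj), 0, tolerance = 1e-12)
  for (j in 1:3) expect_equal(sum(adj * pcs[, j]), 0, tolerance = 1e-8)

  const <- matrix(1, n, 2)
  expect_equal(adjust_score(as.vector(s), const), as.vector(s) - mean(s))

  lin <- as.vector(5 + 3 * pcs[, 1])
  expect_equal(adjust_score(lin, pcs), rep(0, n), tolerance = 1e-10)

  expect_error(adjust_score(as.vector(s), cbind(pcs, pcs[, 1])), "rank-deficient")
})

test_that("splits are stratified, disjoint and reproducible", {
  samples <- data.frame(iid = sprintf("i%03d", 1:100),
                        sex = rep(c("male", "female"), 50),
                        phenotype = rep(c(1, 0), c(30, 70)))
  sp <- split_train_test(samples, 0.8, seed = 9)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_equal(sum(samples$phenotype[sp$train]), 24)   # 0.8 * 30 cases
  expect_identical(sp, split_train_test(samples, 0.8, seed = 9))
  expect_false(identical(sp, split_train_test(samples, 0.8, seed = 10)))
  few <- samples[c(1:3, 31:35), ]     # 3 cases, 5 controls
  expect_error(split_train_test(few, 0.8, seed = 1), "too small")
})

test_that("AUC equals the all-pairs oracle and behaves at the null", {
  set.seed(52)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4)
  s[3] <- s[4]                                   # force a tie
  expect_equal(evaluate_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
  expect_equal(evaluate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(evaluate_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  null_s <- rnorm(2000); null_y <- rbinom(2000, 1, 0.3)
  expect_gt(evaluate_auc(null_s, null_y), 0.45)
  expect_lt(evaluate_auc(null_s, null_y), 0.55)
  expect_error(evaluate_auc(s, rep(1, 200)), "both classes")
})

test_that("threshold selection walks the grid and reproduces bit-for-bit", {
  panel <- rand_panel(200, 30, seed = 53, maf = 0.3)
  set.seed(53)
  liab <- as.vector(scale(panel$dosages[, 1:5]) %*% rep(0.4, 5)) + rnorm(200)
  panel$samples$phenotype <- as.numeric(liab > quantile(liab, 0.7))
  panel <- compute_pcs(panel, k = 4, thin_cm = NULL)
  hw <- fake_harmonized(panel, seed = 53,
                        p = c(rep(1e-6, 5), runif(25, 0.05, 1)),
                        beta = c(rep(0.4, 5), rnorm(25, 0, 0.02)))
  clumped <- clump(hw, panel, clump_config(window_cm = 0.01, r2_max = 0.99))

  single <- select_threshold(clumped, panel, grid = 0.5, seed = 2)
  expect_equal(single$chosen, 0.5)

  sel <- select_threshold(clumped, panel, seed = 2)
  expect_s3_class(sel, "threshold_selection")
  expect_true(all(sel$selection$n_snps > 0))
  expect_equal(nrow(sel$selection),
               sum(sapply(threshold_grid(), function(t) any(hw$p <= t))))
  expect_true(sel$chosen %in% sel$selection$threshold)
  expect_equal(max(sel$selection$auc_test),
               sel$selection$auc_test[sel$selection$threshold == sel$chosen])

  sel2 <- select_threshold(clumped, panel, seed = 2)
  expect_identical(sel$selection, sel2$selection)
  expect_identical(sel$adjusted, sel2$adjusted)

  log_sel <- select_threshold(clumped, panel, seed = 2, evaluator = "logistic")
  expect_true(log_sel$chosen %in% threshold_grid())
})

test_that("pathway restriction subsets entries and preserves whole-genome scores", {
  fx <- clumped_fixture()
  model <- build_model(fx$clumped, 0.5)
  genome <- data.frame(chr = 1, start = 0, end = 1e9, name = "all")
  whole <- pathway_subset(model, genome, "everything")
  expect_equal(score_prs(fx$panel, whole), score_prs(fx$panel, model))
  expect_equal(whole$provenance$pathway, "everything")

  none <- data.frame(chr = 2, start = 0, end = 1e9, name = "off")
  expect_error(pathway_subset(model, none), "no model SNPs")

  # entries sit at bp = 1e5 * (1..12); plant intervals catching 4 of them
  four <- data.frame(chr = 1, start = c(0, 5e5), end = c(2e5, 7.5e5),
                     name = c("gA", "gB"))
  sub <- pathway_subset(model, four, "four")
  expect_equal(sort(sub$entries$snp), c("s001", "s002", "s006", "s007"))
})
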