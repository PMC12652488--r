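test_that("ld_r2 matches the Pearson formula and handles degenerate variants", {
  panel <- rand_panel(50, 10, seed = 31, maf = 0.3)
  expect_equal(ld_r2(panel, "s001", "s001"), 1)
  g <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  p2 <- genotype_panel(
    g, data.frame(snp = c("x", "y"), chr = 1, bp = c(100, 200), a1 = "A", a2 = "G"),
    data.frame(iid = letters[1:4], sex = "male", phenotype = NA))
  expect_equal(ld_r2(p2, "x", "y"), 0)
  for (pair in list(c(1, 2), c(3, 7), c(4, 9))) {
    a <- panel$variants$snp[pair[1]]; b <- panel$variants$snp[pair[2]]
    expect_equal(ld_r2(panel, a, b),
                 cor(panel$dosages[, pair[1]], panel$dosages[, pair[2]])^2,
                 tolerance = 1e-12)
  }
  panel$dosages[, 2] <- 1
  expect_equal(ld_r2(panel, "s001", "s002"), 0)
  expect_error(ld_r2(panel, "s001", "nope"), "not in panel")
})

test_that("forced two-SNP configurations clump as the algorithm dictates", {
  panel <- rand_panel(40, 1, seed = 32)
  hw <- fake_harmonized(panel, p = 0.01)
  res <- clump(hw, panel, clump_config())
  expect_equal(res$index$snp, "s001")
  expect_equal(nrow(res$assignments), 0)

  p2 <- rand_panel(40, 2, seed = 33)
  p2$dosages[, 2] <- p2$dosages[, 1]             # r2 = 1
  p2$variants$cm <- c(0, 1)                      # 1 cM apart
  hw2 <- fake_harmonized(p2, p = c(1e-6, 1e-3))
  res2 <- clump(hw2, p2, clump_config(window_cm = 3))
  expect_equal(res2$index$snp, "s001")
  expect_equal(res2$assignments,
               data.frame(snp = "s002", index_snp = "s001",
                          stringsAsFactors = FALSE))
})

test_that("clumping partitions the input and orders index SNPs by p", {
  panel <- rand_panel(100, 60, seed = 34, chr = rep(c(1, 2), each = 30))
  hw <- fake_harmonized(panel, seed = 34)
  res <- clump(hw, panel, clump_config(window_cm = 1, r2_max = 0.05))
  all_snps <- sort(c(res$index$snp, res$assignments$snp))
  expect_equal(all_snps, sort(hw$snp))                    # partition
  expect_true(all(diff(res$index$p) >= 0))                # selection order
  expect_true(all(res$assignments$index_snp %in% res$index$snp))
  # absorbed SNPs are within the window of their index on the same chromosome
  ai <- match(res$assignments$snp, hw$snp)
  bi <- match(res$assignments$index_snp, hw$snp)
  expect_true(all(hw$chr[ai] == hw$chr[bi]))
  expect_true(all(abs(hw$cm[ai] - hw$cm[bi]) <= 1))
})

test_that("absorption can be disabled and exclusion drops region SNPs", {
  panel <- rand_panel(60, 20, seed = 35)
  panel$dosages[, 2] <- panel$dosages[, 1]
  hw <- fake_harmonized(panel, seed = 35)
  res <- clump(hw, panel, clump_config(r2_max = 1 + 1e-9))
  expect_equal(sort(res$index$snp), sort(hw$snp))         # everyone is index

  panel6 <- rand_panel(60, 20, seed = 36, chr = 6)
  hw6 <- fake_harmonized(panel6, seed = 36)
  cfg <- clump_config(exclude_region = c(6, 1, 5e5))      # covers s001..s005
  res6 <- clump(hw6, panel6, cfg)
  expect_false(any(sprintf("s%03d", 1:5) %in%
                     c(res6$index$snp, res6$assignments$snp)))
  expect_equal(sort(res6$excluded), sprintf("s%03d", 1:5))
})

test_that("greedy clumping equals the exhaustive reference on random panels", {
  for (seed in 1:4) {
    panel <- rand_panel(80, 40, seed = 40 + seed,
                        chr = rep(c(1, 2), each = 20))
    # overlay LD: copy neighbours with noise to create absorbable pairs
    for (j in seq(2, 40, by = 3)) {
      flip <- rbinom(80, 1, 0.1)
      panel$dosages[, j] <- pmin(2, pmax(0, panel$dosages[, j - 1] + flip))
    }
    hw <- fake_harmonized(panel, seed = 40 + seed)
    cfg <- clump_config(window_cm = 1.5, r2_max = 0.2)
    res <- clump(hw, panel, cfg)
    ref <- clump_oracle(hw, panel, cfg)
    expect_equal(res$index$snp, ref$index)
    expect_equal(res$assignments[order(res$assignments$snp), ],
                 ref$assignments[order(ref$assignments$snp), ],
                 ignore_attr = TRUE)
  }
})

test_that("uniform-map genetic clumping reproduces physical clumping", {
  panel <- rand_panel(80, 50, seed = 45)
  panel$variants$cm <- panel$variants$bp / 1e6    # exactly 1 cM per Mb
  hw <- fake_harmonized(panel, seed = 45)
  g <- clump(hw, panel, clump_config(window_cm = 3, mode = "genetic"))
  p <- clump(hw, panel, clump_config(window_kb = 3000, mode = "physical"))
  expect_equal(g$index$snp, p$index$snp)
  expect_equal(g$assignments, p$assignments)
})

test_that("HLA fraction counts retained SNPs inside the region", {
  panel <- rand_panel(50, 10, seed = 46, chr = c(rep(6, 4), rep(2, 6)))
  panel$variants$bp <- c(26e6, 27e6, 28e6, 40e6, 1:6 * 1e6)
  hw <- fake_harmonized(panel, seed = 46)
  res <- clump(hw, panel, clump_config(window_cm = 0.001, r2_max = 0.999))
  expect_equal(hla_fraction(res, hla_region()), 0.3)  # 3 of 10 planted inside
  res$index <- res$index[res$index$chr == 2, ]
  expect_equal(hla_fraction(res, hla_region()), 0)
})

test_that("gene interval counting honours the BED half-open convention", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tgA", "1\t500\t1000\tgB", "2\t0\t10000\tgC"), bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$chr, c(1, 1, 2))
  snps <- data.frame(snp = c("a", "b", "c"), chr = c(1, 1, 1),
                     bp = c(100, 99, 501))
  cnt <- gene_enrichment(snps, iv)
  expect_equal(cnt$n_snps[cnt$name == "gA"], 1)   # bp 100 in (99, 100]
  expect_equal(cnt$n_snps[cnt$name == "gB"], 1)
  expect_equal(cnt$n_snps[cnt$name == "gC"], 0)

  set.seed(47)
  snps2 <- data.frame(snp = sprintf("r%02d", 1:20), chr = 1,
                      bp = c(sample(1001:2000, 5), sample(5001:6000, 3),
                             sample(20000:30000, 12)))
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t1000\t2000\tg1", "1\t5000\t6000\tg2", "1\t8000\t9000\tg3"),
             bed2)
  cnt2 <- gene_enrichment(snps2, read_bed_intervals(bed2))
  expect_equal(cnt2$n_snps, c(5, 3, 0))
  expect_equal(attr(cnt2, "top")$name[1], "g1")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tok", "1\tnope\t300\tbad"), bad)
  expect_error(read_bed_intervals(bad), "line 2")
})
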