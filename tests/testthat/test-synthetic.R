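small_cfg <- function(...) {
  sim_config(n_discovery = 300, n_target = 300, n_snps_per_chr = 100, ...)
}

test_that("simulated maps compress the block below 3 cM at 1 cM/Mb background", {
  cfg <- sim_config()
  maps <- simulate_map(cfg)
  m6 <- maps[["6"]]
  b <- cfg$block
  span_cm <- interpolate_cm(m6, b$end) - interpolate_cm(m6, b$start)
  expect_gt(b$end - b$start, 250e3)              # far wider than a 250 kb window
  expect_lt(span_cm, 3)
  expect_equal(span_cm, 8 * b$rate_cm_per_mb)
  # outside the block the rate is 1 cM/Mb
  expect_equal(interpolate_cm(m6, 10e6) - interpolate_cm(m6, 9e6), 1)
  m1 <- maps[["1"]]
  expect_equal(interpolate_cm(m1, 51e6) - interpolate_cm(m1, 50e6), 1)
  for (mm in maps) {
    expect_true(all(diff(mm$bp) > 0))
    expect_true(all(diff(mm$cm) >= 0))
  }
})

test_that("genotype draws respect their MAFs, HWE and the block LD contrast", {
  cfg <- sim_config(n_target = 2000, n_discovery = 50, n_snps_per_chr = 150)
  maps <- simulate_map(cfg)
  geno <- simulate_genotypes(cfg, maps, seed = 71)
  tgt <- geno$target
  expect_equal(dim(tgt$dosages), c(2000, 450))
  emp <- panel_freq(tgt)
  expect_lt(max(abs(emp - geno$variants$maf)), 0.03)

  # in-block adjacent pairs are in much stronger LD than cross-block pairs
  vb <- which(geno$variants$in_block)
  r2_adj <- sapply(head(seq_along(vb), 20)[-1], function(k)
    cor(tgt$dosages[, vb[k - 1]], tgt$dosages[, vb[k]])^2)
  off <- which(geno$variants$chr == 1)
  r2_far <- sapply(1:20, function(k)
    cor(tgt$dosages[, off[k]], tgt$dosages[, off[k + 50]])^2)
  expect_gt(mean(r2_adj), mean(r2_far) + 0.2)

  # null HWE calibration
  counts <- apply(tgt$dosages[, 1:150], 2, function(g)
    c(sum(g == 0), sum(g == 1), sum(g == 2)))
  hwe_p <- apply(counts, 2, function(cc) hwe_exact_test(cc[1], cc[2], cc[3]))
  expect_lt(mean(hwe_p < 0.05), 0.10)
})

test_that("liability phenotypes hit the prevalence and separate by liability", {
  cfg <- sim_config(n_target = 5000, n_discovery = 50, n_snps_per_chr = 100)
  maps <- simulate_map(cfg)
  geno <- simulate_genotypes(cfg, maps, seed = 72)
  causal <- draw_causal_effects(cfg, geno$variants, seed = 72)
  expect_equal(nrow(causal), cfg$n_causal)
  in_block <- causal$snp %in% geno$variants$snp[geno$variants$in_block]
  expect_equal(sum(in_block), round(cfg$n_causal * cfg$prop_causal_block))
  tgt <- simulate_phenotype(geno$target, cfg, causal, seed = 72)
  expect_lt(abs(mean(tgt$samples$phenotype) - cfg$prevalence), 0.02)
  expect_gt(mean(tgt$samples$true_score[tgt$samples$phenotype == 1]),
            mean(tgt$samples$true_score[tgt$samples$phenotype == 0]))
  expect_setequal(unique(tgt$samples$sex), c("male", "female"))
})

test_that("null heritability severs the genotype-phenotype link", {
  cfg <- small_cfg(h2_liability = 0)
  st <- simulate_study(cfg, seed = 73)
  expect_equal(sd(st$target$samples$true_score), 0)
  g1 <- st$target$dosages[, 1]
  expect_gt(t.test(g1 ~ st$target$samples$phenotype)$p.value, 0.01)
})

test_that("discovery GWAS ranks causal SNPs above null SNPs and is calibrated", {
  cfg <- sim_config(n_discovery = 1500, n_target = 50, n_snps_per_chr = 400,
                    chromosomes = c(1, 6), ld_decay_cm = 1e-4)  # ~independent SNPs
  maps <- simulate_map(cfg)
  geno <- simulate_genotypes(cfg, maps, seed = 74)
  causal <- draw_causal_effects(cfg, geno$variants, seed = 74)
  disc <- simulate_phenotype(geno$discovery, cfg, causal, seed = 74)
  ss <- simulate_sumstats(disc, seed = 74)
  z <- abs(ss$beta / ss$se)
  is_causal <- ss$snp %in% causal$snp
  expect_gt(mean(z[is_causal]), mean(z[!is_causal]) + 1)
  # null p-values are roughly uniform (LD off; block SNPs excluded since the
  # background correlation floor lets them tag in-block causal effects)
  null_p <- ss$p[!is_causal & ss$chr == 1]
  expect_gt(mean(null_p < 0.05), 0.03)
  expect_lt(mean(null_p < 0.05), 0.08)
  # orientation flips leave harmonized weights identical
  hw <- harmonize(ss, disc)
  unflipped <- ss
  swap <- unflipped$a1 != disc$variants$a1[match(unflipped$snp, disc$variants$snp)]
  unflipped[swap, c("a1", "a2")] <- unflipped[swap, c("a2", "a1")]
  unflipped$beta[swap] <- -unflipped$beta[swap]
  expect_equal(harmonize(unflipped, disc)$beta, hw$beta)
})

test_that("metabolite couplings follow their configured sex directions", {
  cfg <- sim_config(n_target = 3000, n_discovery = 50, n_snps_per_chr = 60,
                    metabolite_missing_rate = 0)
  maps <- simulate_map(cfg)
  geno <- simulate_genotypes(cfg, maps, seed = 75)
  causal <- draw_causal_effects(cfg, geno$variants, seed = 75)
  tgt <- simulate_phenotype(geno$target, cfg, causal, seed = 75)
  met <- simulate_metabolites(tgt, cfg, seed = 75)
  expect_false(anyNA(met$values))
  s <- tgt$samples$true_score
  male <- tgt$samples$sex == "male"
  expect_gt(cor(s[male], met$values[male, "hdl_c"]), 0.1)
  expect_lt(cor(s[!male], met$values[!male, "hdl_c"]), -0.1)
  expect_lt(abs(cor(s, met$values[, "null_met"])), 0.05)

  cats <- categorize(s, tgt$samples$sex)
  kt <- kendall_tau_b(cats[male], met$values[male, "null_met"])
  expect_lt(abs(kt$tau_b), 0.05)

  cfg_miss <- sim_config(metabolite_missing_rate = 0.1, n_target = 3000,
                         n_discovery = 50, n_snps_per_chr = 60)
  met2 <- simulate_metabolites(tgt, cfg_miss, seed = 76)
  expect_gt(mean(is.na(met2$values)), 0.05)
})

test_that("the whole study generator is deterministic under a fixed seed", {
  a <- simulate_study(small_cfg(), seed = 77)
  b <- simulate_study(small_cfg(), seed = 77)
  expect_identical(a$target$dosages, b$target$dosages)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(a$truth$causal, b$truth$causal)
  c_ <- simulate_study(small_cfg(), seed = 78)
  expect_false(identical(a$target$dosages, c_$target$dosages))
})

test_that("generated files round-trip through the package readers", {
  st <- simulate_study(small_cfg(), seed = 79)
  dir <- withr::local_tempdir()
  write_plink(st$target, file.path(dir, "target"))
  back <- read_plink(file.path(dir, "target"))
  expect_equal(back$dosages, st$target$dosages)
  expect_equal(back$samples$phenotype, st$target$samples$phenotype)

  bed <- file.path(dir, "genes.bed")
  write_bed_intervals(st$intervals, bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$name, st$intervals$name)
  expect_equal(iv$start, st$intervals$start)
})
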