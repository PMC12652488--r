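# Synthetic study generator. Emulates the data shapes the pipeline consumes:
# piecewise-linear genetic maps with a depressed-recombination "HLA-like"
# block on chromosome 6 (8 Mb of physical span compressed into < 3 cM),
# Gaussian-copula genotypes whose latent correlation decays with genetic
# distance, a liability-threshold case/control phenotype, a discovery-cohort
# single-variant GWAS, gene/pathway intervals, and quantitative metabolites
# coupled to the true genetic score with sex-specific directions.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study the package's validation runs on:
#' two independent cohorts of 2,000 samples (discovery for the GWAS, target
#' for PRS construction), 3 chromosomes x 500 SNPs with 1 cM/Mb background
#' recombination, and an 8 Mb block on chromosome 6 (25-33 Mb) where the
#' recombination rate drops to 0.125 cM/Mb so the block spans 1 cM. Because
#' latent correlation decays with genetic distance, the flat map stretches
#' strong LD across megabases of the block (r-squared above the clumping
#' threshold out to roughly 2.5 Mb) while still leaving several mutually
#' weakly-correlated sub-signals inside it — the architecture under which
#' HLA-inclusive fitted models retain many HLA SNPs; `block$rho` adds an
#' elevated background correlation floor below the clumping threshold.
#' Disease liability is h2 = 0.5 heritable
#' over 30 causal SNPs, 60% of them inside the block (the causal density the
#' fitted-SNP HLA fractions of autoimmune GWAS suggest), with 15% prevalence
#' as in a case-enriched case-control cohort.
#'
#' @param n_discovery,n_target cohort sizes.
#' @param chromosomes autosome labels simulated (block chromosome must be
#'   included).
#' @param n_snps_per_chr SNPs per chromosome.
#' @param chr_length_bp physical chromosome length.
#' @param maf_range range minor allele frequencies are drawn from.
#' @param ld_decay_cm e-folding scale (cM) of the latent correlation.
#' @param block list: `chr`, `start`, `end` (bp), `rate_cm_per_mb` (local
#'   recombination rate), `rho` (latent correlation floor inside the block),
#'   `snp_frac` (fraction of the block chromosome's SNPs placed inside).
#' @param n_causal number of causal SNPs.
#' @param prop_causal_block fraction of causal SNPs inside the block.
#' @param h2_liability heritability on the liability scale.
#' @param prevalence disease prevalence K.
#' @param sex_effect_ratio multiplier applied to male causal effects
#'   (1 = no sex-specific genetic effect).
#' @param sumstats_engine `"linear"` (vectorized score-type regression on
#'   the 0/1 phenotype, the default) or `"logistic"` (per-SNP glm).
#' @param metabolites data.frame `name`, `d_male`, `d_female` (directions in
#'   -1/0/+1), `gamma` (effect magnitude) defining each metabolite's
#'   coupling to the standardized true genetic score.
#' @param metabolite_missing_rate completely-at-random missingness rate.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_discovery = 2000, n_target = 2000,
                       chromosomes = c(1, 2, 6), n_snps_per_chr = 500,
                       chr_length_bp = 1e8, maf_range = c(0.05, 0.5),
                       ld_decay_cm = 0.3,
                       block = list(chr = 6, start = 25e6, end = 33e6,
                                    rate_cm_per_mb = 0.125, rho = 0.3,
                                    snp_frac = 0.3),
                       n_causal = 30, prop_causal_block = 0.6,
                       h2_liability = 0.5, prevalence = 0.15,
                       sex_effect_ratio = 1,
                       sumstats_engine = c("linear", "logistic"),
                       metabolites = default_metabolite_spec(),
                       metabolite_missing_rate = 0.05) {
  stopifnot(prevalence > 0, prevalence < 1, h2_liability >= 0, h2_liability < 1,
            block$rho > 0, block$rho < 1, block$chr %in% chromosomes,
            block$end > block$start)
  structure(list(n_discovery = n_discovery, n_target = n_target,
                 chromosomes = chromosomes, n_snps_per_chr = n_snps_per_chr,
                 chr_length_bp = chr_length_bp, maf_range = maf_range,
                 ld_decay_cm = ld_decay_cm, block = block,
                 n_causal = n_causal, prop_causal_block = prop_causal_block,
                 h2_liability = h2_liability, prevalence = prevalence,
                 sex_effect_ratio = sex_effect_ratio,
                 sumstats_engine = match.arg(sumstats_engine),
                 metabolites = metabolites,
                 metabolite_missing_rate = metabolite_missing_rate),
            class = "sim_config")
}

#' Default metabolite coupling specification
#'
#' Six lipid-metabolite stand-ins: an HDL-like trait with opposite-signed
#' coupling in males and females, LDL/VLDL-triglyceride-like traits with a
#' shared positive coupling, PUFA-like traits decreasing with genetic risk,
#' a MUFA-like trait increasing, and one null trait.
#'
#' @return data.frame `name`, `d_male`, `d_female`, `gamma`.
#' @export
default_metabolite_spec <- function() {
  data.frame(
    name = c("hdl_c", "ldl_tg", "vldl_tg", "omega3_ratio", "mufa_ratio", "null_met"),
    d_male = c(+1, +1, +1, -1, +1, 0),
    d_female = c(-1, +1, +1, -1, +1, 0),
    gamma = c(0.3, 0.3, 0.2, 0.25, 0.25, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate genetic maps
#'
#' Piecewise-linear maps at 1 cM/Mb genome-wide, except inside the
#' configured block where the local rate is `block$rate_cm_per_mb`, so the
#' 8 Mb default block spans 1 cM.
#'
#' @param config a [sim_config()].
#' @return a `genetic_map_set`.
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chr_length_bp
  b <- config$block
  maps <- list()
  for (c_ in config$chromosomes) {
    if (c_ == b$chr) {
      cm_start <- (b$start - 1) / 1e6
      cm_end <- cm_start + (b$end - b$start) / 1e6 * b$rate_cm_per_mb
      maps[[as.character(c_)]] <- new_genetic_map(
        c_, bp = c(1, b$start, b$end, L),
        cm = c(0, cm_start, cm_end, cm_end + (L - b$end) / 1e6))
    } else {
      maps[[as.character(c_)]] <- new_genetic_map(c_, bp = c(1, L), cm = c(0, (L - 1) / 1e6))
    }
  }
  structure(maps, class = "genetic_map_set")
}

# Per-chromosome latent correlation: exp(-|dcm|/decay), floored at rho for
# pairs both inside the block; eigenvalue-clipped back to a valid
# correlation matrix, then Cholesky-factorized.
.latent_chol <- function(cm, in_block, decay, rho) {
  R <- exp(-abs(outer(cm, cm, "-")) / decay)
  if (any(in_block)) {
    floor_ <- outer(in_block, in_block, "&")
    R[floor_] <- pmax(R[floor_], rho)
  }
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    ei <- eigen(R, symmetric = TRUE)
    val <- pmax(ei$values, 1e-8)
    R <- ei$vectors %*% (val * t(ei$vectors))
    R <- stats::cov2cor(R)
    ch <- chol(R)
  }
  ch
}

# Draw an n x m genotype matrix: two latent haplotype draws per sample,
# thresholded at qnorm(maf), summed -> Hardy-Weinberg dosages with LD.
.draw_genotypes <- function(n, chol_list, thr) {
  cols <- lapply(chol_list, function(ch) {
    m <- ncol(ch)
    h1 <- matrix(stats::rnorm(n * m), n, m) %*% ch
    h2 <- matrix(stats::rnorm(n * m), n, m) %*% ch
    (h1 < rep(thr[[attr(ch, "chr")]], each = n)) +
      (h2 < rep(thr[[attr(ch, "chr")]], each = n))
  })
  do.call(cbind, cols)
}

#' Simulate LD-structured genotype cohorts
#'
#' Draws a discovery and a target cohort independently from the same latent
#' Gaussian-copula structure: within each chromosome the latent correlation
#' is `exp(-|delta cM| / ld_decay_cm)`, floored at `block$rho` for pairs
#' inside the block; two latent draws per sample are thresholded at each
#' SNP's drawn MAF, giving Hardy-Weinberg genotype proportions.
#'
#' @param config a [sim_config()].
#' @param maps maps from [simulate_map()].
#' @param seed integer seed (all randomness is derived from it).
#' @return list with `discovery` and `target` [genotype_panel()]s and
#'   `variants` (the shared variant table with drawn `maf` and `in_block`).
#' @export
simulate_genotypes <- function(config, maps, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$block
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    vlist <- list()
    for (c_ in config$chromosomes) {
      m <- config$n_snps_per_chr
      if (c_ == b$chr) {
        m_in <- round(b$snp_frac * m)
        bp <- sort(c(round(seq(b$start, b$end, length.out = m_in)),
                     sample(setdiff(seq(1e5, config$chr_length_bp, by = 1e5),
                                    seq(b$start, b$end, by = 1e5)), m - m_in)))
      } else {
        bp <- sort(sample(seq(1e5, config$chr_length_bp, by = 1e5), m))
      }
      a1 <- sample(bases, m, replace = TRUE)
      a2 <- vapply(a1, function(a) sample(setdiff(bases, c(a, comp[[a]])), 1), "")
      vlist[[as.character(c_)]] <- data.frame(
        snp = sprintf("rs%d_%04d", c_, seq_len(m)), chr = c_, bp = bp,
        a1 = a1, a2 = unname(a2),
        maf = stats::runif(m, config$maf_range[1], config$maf_range[2]),
        stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, vlist)
    rownames(variants) <- NULL
    variants$cm <- NA_real_
    variants$in_block <- variants$chr == b$chr &
      variants$bp >= b$start & variants$bp <= b$end
    chol_list <- list()
    thr <- list()
    for (c_ in config$chromosomes) {
      idx <- variants$chr == c_
      cm <- interpolate_cm(maps[[as.character(c_)]], variants$bp[idx])
      variants$cm[idx] <- cm
      ch <- .latent_chol(cm, variants$in_block[idx], config$ld_decay_cm, b$rho)
      attr(ch, "chr") <- as.character(c_)
      chol_list[[as.character(c_)]] <- ch
      thr[[as.character(c_)]] <- stats::qnorm(variants$maf[idx])
    }
    make_panel <- function(n, prefix) {
      dos <- .draw_genotypes(n, chol_list, thr)
      samples <- data.frame(iid = sprintf("%s%05d", prefix, seq_len(n)),
                            sex = NA_character_, phenotype = NA_real_,
                            stringsAsFactors = FALSE)
      genotype_panel(dos, variants[, c("snp", "chr", "bp", "a1", "a2", "cm")],
                     samples)
    }
    disc <- make_panel(config$n_discovery, "D")
    targ <- make_panel(config$n_target, "T")
    list(discovery = disc, target = targ, variants = variants)
  })
}

#' Draw the causal architecture
#'
#' Samples `n_causal` causal SNPs (`prop_causal_block` of them inside the
#' block) with standard-normal effect sizes on standardized genotypes.
#'
#' @param config a [sim_config()].
#' @param variants the variant table from [simulate_genotypes()] (with
#'   `in_block`).
#' @param seed integer seed.
#' @return data.frame `snp`, `beta`.
#' @export
draw_causal_effects <- function(config, variants, seed = 1) {
  with_seed(seed, {
    n_in <- round(config$n_causal * config$prop_causal_block)
    in_pool <- variants$snp[variants$in_block]
    out_pool <- variants$snp[!variants$in_block]
    snps <- c(sample(in_pool, min(n_in, length(in_pool))),
              sample(out_pool, config$n_causal - min(n_in, length(in_pool))))
    data.frame(snp = snps, beta = stats::rnorm(length(snps)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a liability-threshold phenotype
#'
#' Genetic liability is the causal-weighted sum of standardized dosages,
#' scaled so its variance share equals `h2_liability`; independent Gaussian
#' noise completes the liability, and a sample is a case iff its liability
#' exceeds the `1 - prevalence` quantile. Sex is Bernoulli(0.5). When
#' `sex_effect_ratio != 1`, male genetic liabilities are multiplied by it
#' before rescaling.
#'
#' @param panel a [genotype_panel()] from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param causal data.frame from [draw_causal_effects()].
#' @param seed integer seed.
#' @return the panel with `sex`, `phenotype` and `true_score` (the genetic
#'   liability) filled into `samples`.
#' @export
simulate_phenotype <- function(panel, config, causal, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  with_seed(seed, {
    n <- nrow(panel$dosages)
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    vi <- match(causal$snp, panel$variants$snp)
    if (anyNA(vi)) stop("causal SNPs missing from panel")
    G <- panel$dosages[, vi, drop = FALSE]
    Gs <- scale(G)
    Gs[, attr(Gs, "scaled:scale") == 0] <- 0
    gl <- as.vector(Gs %*% causal$beta)
    if (config$sex_effect_ratio != 1)
      gl[sex == "male"] <- gl[sex == "male"] * config$sex_effect_ratio
    h2 <- config$h2_liability
    if (h2 > 0 && stats::sd(gl) > 0) {
      gl <- sqrt(h2) * gl / stats::sd(gl)
    } else {
      gl <- rep(0, n)
    }
    liab <- gl + sqrt(1 - h2) * stats::rnorm(n)
    panel$samples$sex <- sex
    panel$samples$phenotype <- as.numeric(liab > stats::qnorm(1 - config$prevalence))
    panel$samples$true_score <- gl
    panel
  })
}

#' Simulate discovery-cohort GWAS summary statistics
#'
#' Per-SNP single-variant association of the 0/1 phenotype on dosage. The
#' `"linear"` engine is a vectorized simple linear regression (score-type
#' statistic); `"logistic"` fits one glm per SNP. Monomorphic SNPs are
#' emitted with `beta = 0`, `p = 1`. A seeded ~30% of records are emitted in
#' flipped allele orientation (effect/other swapped, beta negated) to
#' exercise downstream harmonization; this leaves harmonized weights
#' unchanged.
#'
#' @param panel the phenotyped discovery [genotype_panel()].
#' @param engine `"linear"` or `"logistic"`.
#' @param seed seed for the orientation flips.
#' @return a `sumstats` table.
#' @export
simulate_sumstats <- function(panel, engine = c("linear", "logistic"), seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  engine <- match.arg(engine)
  y <- panel$samples$phenotype
  if (anyNA(y)) stop("phenotype must be present to run the discovery GWAS")
  G <- panel$dosages
  n <- length(y)
  if (engine == "linear") {
    xm <- colMeans(G)
    sxx <- colSums(G^2) - n * xm^2
    yc <- y - mean(y)
    sxy <- as.vector(crossprod(G, yc))
    syy <- sum(yc^2)
    mono <- sxx <= 0
    beta <- ifelse(mono, 0, sxy / sxx)
    rss <- pmax(syy - beta * sxy, 0)
    se <- ifelse(mono, 1, sqrt(rss / (n - 2) / ifelse(mono, 1, sxx)))
    tstat <- ifelse(mono | se == 0, 0, beta / se)
    p <- ifelse(mono, 1, 2 * stats::pt(-abs(tstat), df = n - 2))
  } else {
    fits <- apply(G, 2, function(x) {
      if (stats::sd(x) == 0) return(c(0, 1, 1))
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      co <- summary(fit)$coefficients
      if (nrow(co) < 2) return(c(0, 1, 1))
      co[2, c(1, 2, 4)]
    })
    beta <- fits[1, ]; se <- fits[2, ]; p <- fits[3, ]
  }
  v <- panel$variants
  ss <- data.frame(snp = v$snp, chr = v$chr, bp = v$bp, a1 = v$a1, a2 = v$a2,
                   beta = beta, se = se, p = pmin(pmax(p, 1e-300), 1), n = n,
                   stringsAsFactors = FALSE)
  flip <- with_seed(seed, stats::runif(nrow(ss)) < 0.3)
  ss[flip, c("a1", "a2")] <- ss[flip, c("a2", "a1")]
  ss$beta[flip] <- -ss$beta[flip]
  sumstats(ss)
}

#' Simulate PRS-coupled metabolites
#'
#' Each metabolite `m` is `d_{m,sex} * gamma_m * standardize(true score) +
#' N(0, 1)` noise, with per-sex directions from the configuration, plus
#' completely-at-random missingness.
#'
#' @param panel a phenotyped target [genotype_panel()] (provides sex and,
#'   by default, the true score).
#' @param config a [sim_config()].
#' @param true_score optional override for the coupling score.
#' @param seed integer seed.
#' @return a [metabolite_panel()].
#' @export
simulate_metabolites <- function(panel, config, true_score = NULL, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- true_score %||% panel$samples$true_score
  if (is.null(s)) stop("panel has no true_score; run simulate_phenotype first")
  sex <- panel$samples$sex
  n <- length(s)
  z <- if (stats::sd(s) > 0) as.vector(scale(s)) else rep(0, n)
  spec <- config$metabolites
  with_seed(seed, {
    vals <- vapply(seq_len(nrow(spec)), function(j) {
      d <- ifelse(sex == "male", spec$d_male[j], spec$d_female[j])
      d * spec$gamma[j] * z + stats::rnorm(n)
    }, numeric(n))
    colnames(vals) <- spec$name
    rownames(vals) <- panel$samples$iid
    if (config$metabolite_missing_rate > 0)
      vals[matrix(stats::runif(length(vals)) < config$metabolite_missing_rate,
                  nrow(vals))] <- NA
    metabolite_panel(vals, sex)
  })
}

#' Simulate pathway gene intervals
#'
#' BED-convention intervals: an "inflammation" pathway of gene-sized
#' intervals tiling the HLA-like block, plus background genes elsewhere.
#'
#' @param config a [sim_config()].
#' @param n_block_genes,n_background_genes interval counts.
#' @param seed integer seed.
#' @return data.frame `chr`, `start`, `end`, `name` (0-based half-open);
#'   pathway genes are named `infl_*`.
#' @export
simulate_gene_intervals <- function(config, n_block_genes = 8,
                                    n_background_genes = 12, seed = 1) {
  b <- config$block
  edges <- round(seq(b$start - 1, b$end, length.out = n_block_genes + 1))
  block_genes <- data.frame(chr = b$chr, start = edges[-length(edges)],
                            end = edges[-1],
                            name = sprintf("infl_%02d", seq_len(n_block_genes)),
                            stringsAsFactors = FALSE)
  bg <- with_seed(seed, {
    chrs <- sample(config$chromosomes, n_background_genes, replace = TRUE)
    starts <- round(stats::runif(n_background_genes, 0, config$chr_length_bp - 2e6))
    data.frame(chr = chrs, start = starts, end = starts + 1e6,
               name = sprintf("gene_%02d", seq_len(n_background_genes)),
               stringsAsFactors = FALSE)
  })
  rbind(block_genes, bg)
}

#' Write intervals as a BED file
#'
#' @param intervals data.frame `chr`, `start`, `end`, `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("chr", "start", "end", "name")], path,
                     quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Simulate a complete study
#'
#' Generates everything one end-to-end analysis needs: maps, the discovery
#' and target cohorts with phenotypes, discovery summary statistics, gene
#' intervals (with the in-block inflammation pathway) and target-cohort
#' metabolites. All randomness derives from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `config`, `maps`, `discovery`, `target`, `sumstats`,
#'   `metabolites`, `intervals`, `pathway` (the inflammation subset) and
#'   `truth` (causal effects and per-cohort true scores).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  maps <- simulate_map(config)
  geno <- simulate_genotypes(config, maps, seed = child_seed(seed, 1))
  causal <- draw_causal_effects(config, geno$variants, seed = child_seed(seed, 2))
  discovery <- simulate_phenotype(geno$discovery, config, causal,
                                  seed = child_seed(seed, 3))
  target <- simulate_phenotype(geno$target, config, causal,
                               seed = child_seed(seed, 4))
  ss <- simulate_sumstats(discovery, engine = config$sumstats_engine,
                          seed = child_seed(seed, 5))
  metabolites <- simulate_metabolites(target, config, seed = child_seed(seed, 6))
  intervals <- simulate_gene_intervals(config, seed = child_seed(seed, 7))
  list(config = config, maps = maps, discovery = discovery, target = target,
       sumstats = ss, metabolites = metabolites, intervals = intervals,
       pathway = intervals[grepl("^infl_", intervals$name), , drop = FALSE],
       truth = list(causal = causal,
                    true_score_discovery = discovery$samples$true_score,
                    true_score_target = target$samples$true_score))
}
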