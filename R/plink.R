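# PLINK 1 binary (.bed/.bim/.fam) input/output.
#
# The .bed layout is SNP-major: 3 magic bytes (0x6c 0x1b 0x01), then for each
# variant ceiling(n/4) bytes, 4 samples per byte, sample 1 in the lowest two
# bits. Two-bit codes: 00 = hom a1 (dosage 2), 01 = missing, 10 = het,
# 11 = hom a2 (dosage 0). Dosages count the bim's a1 allele.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# code (0..3) -> dosage of a1
.code_to_dosage <- c(2, NA, 1, 0)

# lookup: for each byte value 0..255, the 4 decoded dosages
.bed_lut <- local({
  b <- 0:255
  m <- cbind(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
             bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))
  matrix(.code_to_dosage[m + 1L], nrow = 256L)
})

#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' Sex is read from the fam file (1 = male, 2 = female, other = NA) and
#' phenotype from the case/control coding (1 = control, 2 = case, -9/0 = NA).
#' Dosages count the bim `a1` allele.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "bp", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("not a SNP-major PLINK .bed file: ", bed_path)
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m)
    stop(sprintf(".bed size mismatch: expected %d data bytes, found %d",
                 bpv * m, length(body)))
  # decode all bytes at once, then drop per-variant padding samples
  dec <- .bed_lut[as.integer(body) + 1L, , drop = FALSE]   # (bpv*m) x 4
  dos <- matrix(t(dec), nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  dim(dos) <- c(n, m)
  sex <- c("male", "female")[match(fam$sex, c(1, 2))]
  pheno <- c(0, 1)[match(fam$pheno, c(1, 2))]
  variants <- data.frame(snp = bim$snp, chr = bim$chr, bp = bim$bp,
                         a1 = bim$a1, a2 = bim$a2, cm = bim$cm,
                         stringsAsFactors = FALSE)
  variants$cm[variants$cm == 0] <- NA_real_  # PLINK convention: 0 = unset
  samples <- data.frame(iid = fam$iid, sex = sex, phenotype = pheno,
                        stringsAsFactors = FALSE)
  genotype_panel(dos, variants, samples)
}

#' Write a genotype panel as a PLINK bed/bim/fam fileset
#'
#' @param panel a [genotype_panel()]; fractional (imputed) dosages are not
#'   representable and raise an error.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  if (any(dos[!is.na(dos)] != round(dos[!is.na(dos)])))
    stop("fractional dosages cannot be written to .bed")
  n <- nrow(dos); m <- ncol(dos)
  codes <- matrix(1L, nrow = n, ncol = m)      # 01 = missing
  codes[!is.na(dos) & dos == 2] <- 0L
  codes[!is.na(dos) & dos == 1] <- 2L
  codes[!is.na(dos) & dos == 0] <- 3L
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0) codes <- rbind(codes, matrix(3L, pad, m))  # pad as hom a2
  dim(codes) <- c(4L, nrow(codes) / 4L * m)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ])
  writeBin(c(.bed_magic, bytes), paste0(prefix, ".bed"))

  v <- panel$variants
  cm <- ifelse(is.na(v$cm), 0, v$cm)
  utils::write.table(data.frame(v$chr, v$snp, cm, v$bp, v$a1, v$a2),
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  s <- panel$samples
  sex <- ifelse(is.na(s$sex), 0L, ifelse(s$sex == "male", 1L, 2L))
  ph <- ifelse(is.na(s$phenotype), -9L, ifelse(s$phenotype == 1, 2L, 1L))
  utils::write.table(data.frame(s$iid, s$iid, 0L, 0L, sex, ph),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
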