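# Genetic maps: loading HapMap-style map files and converting physical
# positions (bp) to genetic distances (cM) by piecewise-linear interpolation.

new_genetic_map <- function(chr, bp, cm) {
  structure(data.frame(bp = as.numeric(bp), cm = as.numeric(cm)),
            chromosome = chr, class = c("genetic_map", "data.frame"))
}

#' Load a genetic map file
#'
#' Reads a whitespace/tab-delimited genetic map with columns chromosome,
#' physical position (bp, 1-based) and cumulative genetic position (cM);
#' a HapMap-style rate column (cM/Mb) between bp and cM is detected from the
#' header and ignored. A header line is auto-detected. Chromosome labels
#' "chr1" and "1" are both accepted and normalized; non-autosomal rows are
#' skipped with a warning. Within each chromosome, rows are sorted by
#' position; rows whose cM would decrease below the running maximum are
#' rejected (reported via the `"rejected"` attribute and a warning), and a
#' duplicated position with conflicting cM is an error.
#'
#' @param path map file path.
#' @return a `genetic_map_set`: a named list with one `genetic_map`
#'   (data.frame of `bp`, `cm` knots) per chromosome.
#' @export
load_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(toks) >= 3 &&
    is.na(suppressWarnings(as.numeric(toks[2])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("genetic map must have at least 3 columns (chr, bp, cM): ", path)
  cols <- if (has_header) tolower(names(df)) else character(0)
  if (ncol(df) >= 4 && (length(cols) == 0 || any(grepl("rate", cols)))) {
    # HapMap convention: chr, bp, rate(cM/Mb), cM — drop the rate column
    df <- df[, c(1, 2, 4)]
  } else {
    df <- df[, 1:3]
  }
  names(df) <- c("chr", "bp", "cm")
  if (!is.numeric(df$bp) || !is.numeric(df$cm))
    stop("genetic map bp/cM columns are not numeric: ", path)
  chr <- normalize_chrom(df$chr)
  if (anyNA(chr)) {
    warning(sprintf("skipping %d non-autosomal map rows (%s)", sum(is.na(chr)),
                    paste(unique(df$chr[is.na(chr)]), collapse = ", ")))
    df <- df[!is.na(chr), , drop = FALSE]
    chr <- chr[!is.na(chr)]
  }
  if (!nrow(df)) stop("no autosomal rows in genetic map: ", path)
  maps <- list()
  rejected <- list()
  for (c_ in sort(unique(chr))) {
    sub <- df[chr == c_, , drop = FALSE]
    o <- order(sub$bp, sub$cm)
    if (is.unsorted(sub$bp)) warning(sprintf("chr%d map rows out of order; sorted by position", c_))
    sub <- sub[o, , drop = FALSE]
    dup <- duplicated(sub$bp)
    if (any(dup)) {
      conflict <- dup & sub$cm != sub$cm[match(sub$bp, sub$bp)]
      if (any(conflict))
        stop(sprintf("chr%d: duplicated position %d with conflicting cM values",
                     c_, as.integer(sub$bp[which(conflict)[1]])))
      sub <- sub[!dup, , drop = FALSE]
    }
    keep <- cummax(sub$cm) == sub$cm  # drop rows that would make cM decrease
    if (!all(keep)) rejected[[as.character(c_)]] <- sub[!keep, , drop = FALSE]
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("chr%d has fewer than 2 usable knots; chromosome skipped", c_))
      next
    }
    maps[[as.character(c_)]] <- new_genetic_map(c_, sub$bp, sub$cm)
  }
  if (length(rejected))
    warning(sprintf("rejected %d map rows violating cM monotonicity",
                    sum(vapply(rejected, nrow, 1L))))
  if (!length(maps)) stop("no chromosome in map has >= 2 usable knots: ", path)
  structure(maps, class = "genetic_map_set", rejected = rejected)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Piecewise-linear interpolation between map knots. Positions before the
#' first knot take the first knot's cM and positions beyond the last knot the
#' last knot's cM (clamped extrapolation), so the result is total and
#' monotone non-decreasing in position.
#'
#' @param map a `genetic_map` (one chromosome).
#' @param position numeric vector of 1-based bp positions.
#' @return numeric vector of cM values.
#' @export
interpolate_cm <- function(map, position) {
  stopifnot(inherits(map, "genetic_map"))
  if (nrow(map) < 2) stop("genetic map needs at least 2 knots")
  stats::approx(map$bp, map$cm, xout = position, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Annotate panel variants with genetic positions
#'
#' @param panel a [genotype_panel()].
#' @param maps a `genetic_map_set` from [load_genetic_map()] covering every
#'   chromosome present in the panel.
#' @return the panel with `variants$cm` filled in.
#' @export
annotate_cm <- function(panel, maps) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(maps, "genetic_map_set"))
  chrs <- unique(panel$variants$chr)
  missing_chr <- setdiff(as.character(chrs), names(maps))
  if (length(missing_chr))
    stop("no genetic map for chromosome(s): ", paste(missing_chr, collapse = ", "))
  cm <- panel$variants$cm
  for (c_ in chrs) {
    idx <- panel$variants$chr == c_
    cm[idx] <- interpolate_cm(maps[[as.character(c_)]], panel$variants$bp[idx])
  }
  panel$variants$cm <- cm
  panel
}
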