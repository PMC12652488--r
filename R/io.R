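# Text-format writers/readers for the artifacts the command-line interface
# exchanges: summary statistics, genetic maps and metabolite tables.

#' Write summary statistics to a tab-delimited file
#'
#' Columns are written under the conventional GWAS headers SNP, CHR, BP, A1,
#' A2, BETA, SE, P, N, readable back via [read_sumstats()].
#'
#' @param ss a `sumstats` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  out <- data.frame(SNP = ss$snp, CHR = ss$chr, BP = ss$bp, A1 = ss$a1,
                    A2 = ss$a2, BETA = ss$beta, SE = ss$se, P = ss$p, N = ss$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genetic map set as a map file
#'
#' Three-column chr/bp/cM text readable back via [load_genetic_map()].
#'
#' @param maps a `genetic_map_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(maps, path) {
  stopifnot(inherits(maps, "genetic_map_set"))
  rows <- do.call(rbind, lapply(names(maps), function(c_)
    data.frame(chr = c_, bp = maps[[c_]]$bp, cm = maps[[c_]]$cm)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a metabolite panel as TSV
#'
#' The table holds one row per sample: `iid`, `sex`, then one numeric column
#' per metabolite (empty/NA cells are missing measurements).
#'
#' @param path file path.
#' @return [metabolite_panel()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_metabolites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("iid", "sex") %in% names(df)))
    stop("metabolite file must have iid and sex columns")
  vals <- as.matrix(df[, setdiff(names(df), c("iid", "sex")), drop = FALSE])
  rownames(vals) <- df$iid
  metabolite_panel(vals, df$sex)
}

#' @rdname read_metabolites
#' @param panel a [metabolite_panel()].
#' @export
write_metabolites <- function(panel, path) {
  stopifnot(inherits(panel, "metabolite_panel"))
  out <- data.frame(iid = panel$iid, sex = panel$sex, panel$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Emits the file bundle a shell user would analyse: PLINK bed/bim/fam for
#' both cohorts, the discovery summary statistics, the genetic map, gene and
#' pathway BED intervals, the metabolite table and a truth table of causal
#' effects.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(study$discovery, file.path(dir, "discovery"))
  write_plink(study$target, file.path(dir, "target"))
  write_sumstats(study$sumstats, file.path(dir, "sumstats.tsv"))
  write_genetic_map(study$maps, file.path(dir, "genetic_map.txt"))
  write_bed_intervals(study$intervals, file.path(dir, "genes.bed"))
  write_bed_intervals(study$pathway, file.path(dir, "pathway.bed"))
  write_metabolites(study$metabolites, file.path(dir, "metabolites.tsv"))
  utils::write.table(study$truth$causal, file.path(dir, "causal_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a study from a directory written by [write_study()]
#'
#' @param dir directory containing `target.bed/bim/fam`, `sumstats.tsv`,
#'   `genetic_map.txt` and optionally `metabolites.tsv` / `pathway.bed`.
#' @return a study list consumable by [run_gprs()] / [compare_methods()].
#' @export
read_study <- function(dir) {
  study <- list(
    target = read_plink(file.path(dir, "target")),
    sumstats = read_sumstats(file.path(dir, "sumstats.tsv")),
    maps = load_genetic_map(file.path(dir, "genetic_map.txt")))
  met <- file.path(dir, "metabolites.tsv")
  if (file.exists(met)) study$metabolites <- read_metabolites(met)
  pw <- file.path(dir, "pathway.bed")
  if (file.exists(pw)) study$pathway <- read_bed_intervals(pw)
  study
}
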