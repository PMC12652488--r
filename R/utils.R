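# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All user-facing randomness in the package goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a small offset, staying inside
# the 32-bit integer range R requires for set.seed().
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629L)
}

# Normalize chromosome labels: accepts "chr1", "1", 1; returns integer or NA
# for non-autosomal labels (X, Y, MT, 23+).
normalize_chrom <- function(chr) {
  x <- tolower(trimws(as.character(chr)))
  x <- sub("^chr", "", x)
  out <- suppressWarnings(as.integer(x))
  out[!is.na(out) & (out < 1L | out > 22L)] <- NA_integer_
  out
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
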