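# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic stage seeds fanned out from one master seed.  Kept inside
# 32-bit integer range; the multiplier/offset arithmetic is exact in doubles.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + stage * 8191) %% 2147483629)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_scalar_number(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  as.integer(x)
}

# All tabular output goes through one writer so every file shares the dialect:
# tab-separated, no quoting, '.'-decimal, UTF-8.
write_tsv <- function(df, path, col_names = TRUE) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col_names)
  invisible(path)
}

read_tsv_chr <- function(path, header = TRUE) {
  read.delim(path, header = header, sep = "\t", comment.char = "#",
             colClasses = "character", check.names = FALSE,
             blank.lines.skip = TRUE, stringsAsFactors = FALSE)
}
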