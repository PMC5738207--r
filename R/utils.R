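# Internal helpers shared across modules.

# Evaluate `code` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs in the ambient RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one seed, keeping values in 32-bit
# integer range so they are themselves valid seeds.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

se_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# Canonical unordered-genotype key "a/b" with sorted allele labels.
gt_key <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  ifelse(is.na(a1) | is.na(a2), NA_character_, paste0(lo, "/", hi))
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
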