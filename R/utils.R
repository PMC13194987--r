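#' @importFrom stats pchisq quantile rbinom rgamma rnorm rpois runif sd var
#' @importFrom utils head tail
NULL

# Deterministic child-seed derivation: polynomial string hash of the master
# seed plus a stage label, kept inside the 32-bit signed integer range so it
# is valid for set.seed() on every platform.
child_seed <- function(seed, ...) {
  label <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1
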