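# Internal helpers: typed errors, scoped seeding, string hashing.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif plogis setNames
#' @importFrom utils read.table write.table head
NULL

binpuError <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "binpuError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

formatError      <- function(fmt, ...) binpuError("binpu_format_error", fmt, ...)
conflictError    <- function(fmt, ...) binpuError("binpu_conflict_error", fmt, ...)
parameterError   <- function(fmt, ...) binpuError("binpu_parameter_error", fmt, ...)
consistencyError <- function(fmt, ...) binpuError("binpu_consistency_error", fmt, ...)
contractError    <- function(fmt, ...) binpuError("binpu_contract_error", fmt, ...)
stateError       <- function(fmt, ...) binpuError("binpu_state_error", fmt, ...)
ioError          <- function(fmt, ...) binpuError("binpu_io_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL leaves the global stream alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# One master seed per run; stages offset it so each stage is independently
# reproducible. Kept below 2^31.
stageSeed <- function(master, stage) {
  as.integer((as.numeric(master) + stage) %% .Machine$integer.max)
}

pairKey <- function(compound_id, protein_id) {
  paste(compound_id, protein_id, sep = "\x1f")
}

# Stable lexicographic order independent of locale.
lexOrder <- function(...) order(..., method = "radix")

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    parameterError("'%s' must be TRUE or FALSE", name)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    parameterError("'%s' must be a single integer >= %d", name, min)
}

assertNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    parameterError("'%s' must be a single number in [%s, %s]", name,
                   format(min), format(max))
}

# Polynomial rolling hash over byte codes, exact in double arithmetic
# (values stay below 2^37 before each reduction mod 2^32). All tokens must
# share the same number of characters. Returns 1-based buckets plus a sign
# bit taken from higher-order hash bits (signed hashing cancels collision
# noise in expectation).
hashTokens <- function(tokens, dim, seed) {
  n <- length(tokens)
  if (n == 0L) return(list(bucket = integer(0), sign = numeric(0)))
  k <- nchar(tokens[[1L]])
  M <- 2^32
  codes <- vapply(tokens, utf8ToInt, integer(k))
  if (k == 1L) codes <- matrix(codes, nrow = 1L)
  h <- rep((as.numeric(seed) %% M), n)
  for (i in seq_len(k)) h <- (h * 31 + codes[i, ]) %% M
  list(bucket = as.integer(h %% dim) + 1L,
       sign = ifelse(((h %/% dim) %% 2) == 0, 1, -1))
}

# Signed hashed bag-of-tokens, L2-normalized.
hashedCountVector <- function(tokens, dim, seed) {
  v <- numeric(dim)
  if (length(tokens) == 0L) return(v)
  tab <- table(tokens)
  hs <- hashTokens(names(tab), dim, seed)
  contrib <- rowsum(hs$sign * as.numeric(tab), hs$bucket)
  v[as.integer(rownames(contrib))] <- contrib[, 1L]
  l2 <- sqrt(sum(v^2))
  if (l2 > 0) v / l2 else v
}

overlappingTokens <- function(x, width) {
  L <- nchar(x)
  if (L < width)
    binpuError("binpu_featurization_error",
               "string of length %d is shorter than the token width %d", L, width)
  starts <- seq_len(L - width + 1L)
  substring(x, starts, starts + width - 1L)
}
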