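# Internal helpers shared across modules.

DAYS_PER_YEAR <- 365.25

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministically derive a child seed from a master seed and a label, so
# every stochastic component gets its own stream.  Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 1664525 + 12345) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

abort_dcbr <- function(msg, class, ...) {
  stop(structure(class = c(class, "dentalcbr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
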