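#' @keywords internal
"_PACKAGE"

# Argument checking helpers shared across modules. All throw classed
# conditions so callers (and tests) can distinguish user error from bugs.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("hippograd_invalid_argument", "error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    stop_invalid(name, " must be a single integral value")
  }
  if (x < min) stop_invalid(name, " must be >= ", min)
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_invalid(name, " must be in [", lower, ", ", upper, "]")
  }
  as.numeric(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic RNG scoping: run `expr` under `seed` without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Pearson correlation between the rows of two matrices (rows x time), with
# zero-variance rows yielding 0 plus a warning rather than NaN.
row_cor <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  sda <- apply(a, 1L, stats::sd)
  sdb <- apply(b, 1L, stats::sd)
  bad_a <- which(sda == 0)
  bad_b <- which(sdb == 0)
  r <- suppressWarnings(stats::cor(t(a), t(b)))
  if (length(bad_a) || length(bad_b)) {
    warning("zero-variance series detected; their correlations set to 0",
            call. = FALSE)
    if (length(bad_a)) r[bad_a, ] <- 0
    if (length(bad_b)) r[, bad_b] <- 0
  }
  r
}
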