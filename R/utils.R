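## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All stochastic operations in the package funnel through this helper so a
#' caller's RNG stream is never disturbed and equal seeds give equal output.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a stream label, keeping the
## result inside the positive 32-bit integer range.
childSeed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483561
  as.integer(h + 1L)
}

## Stop with a message naming the offending argument.
assertScalarIn <- function(x, name, lower = -Inf, upper = Inf,
                           integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must lie in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}

## Largest-remainder apportionment of n items over proportions p.
largestRemainder <- function(n, p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
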