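# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG state without clobbering the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

assert_matrix_named <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_(sprintf("`%s` must be a numeric matrix", name))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_(sprintf("`%s` must have both row and column names", name))
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop_(sprintf("`%s` has duplicated row or column names", name))
  }
  if (!all(is.finite(x))) {
    stop_(sprintf("`%s` contains non-finite values", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
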