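# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

assert_fraction <- function(x, name, lower = 0, upper = 1,
                            lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%s, %s%s",
                 name, if (lower_open) "(" else "[", format(lower),
                 format(upper), if (upper_open) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

# model.matrix without intercept column, built from character covariate terms
# (supports "I(age^2)", "age:sex", factors).
design_matrix <- function(data, terms) {
  if (length(terms) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  f <- stats::reformulate(terms)
  mf <- stats::model.frame(f, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(f, mf)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}
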