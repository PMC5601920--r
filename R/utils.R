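#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# internal: stop with a classed condition so callers can test error types
pb_abort <- function(message, class) {
  abort(message, class = c(class, "pbodyscreen_error"))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pb_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "pb_missing_columns"
    )
  }
  invisible(df)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    pb_abort(sprintf("`%s` must be numeric in [0, 1]", name), "pb_bad_probability")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    pb_abort(sprintf("`%s` must be a single integer >= %d", name, min), "pb_bad_count")
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    pb_abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
             "pb_bad_number")
  }
  invisible(x)
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}
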