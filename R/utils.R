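#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation errors carry a dedicated condition class so the CLI can map
# them to exit code 2 while real bugs still crash loudly.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hypoatlas_validation_error", "error")))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    abort_validation("`%s` must be > %s", name, lower)
  if (!strict_lower && x < lower)
    abort_validation("`%s` must be >= %s", name, lower)
  if (strict_upper && x >= upper)
    abort_validation("`%s` must be < %s", name, upper)
  if (!strict_upper && x > upper)
    abort_validation("`%s` must be <= %s", name, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort_validation("`%s` must be an integer", name)
  as.integer(x)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_validation("%s is missing required field(s): %s", what,
                     paste(missing, collapse = ", "))
  invisible(df)
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library internals never perturb user-level streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dense row-rank helpers --------------------------------------------------

as_dense_matrix <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

euclidean_dist <- function(a, b) sqrt(sum((a - b)^2))
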