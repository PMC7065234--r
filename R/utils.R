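# Mass of a proton (Da); positive-ion charging assumed throughout.
PROTON_MASS <- 1.00728

abort_param <- function(msg, ...) {
  abort(msg, class = "lipidex_error_parameter", ...)
}

abort_input <- function(msg, ...) {
  abort(msg, class = "lipidex_error_input", ...)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`, then
#' restores the previous RNG state, so seeded generators never perturb the
#' caller's random stream. With `seed = NULL` the current stream is used.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_param("`seed` must be a single finite number or NULL.")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  if (!is.null(strict_min) && x <= strict_min) {
    abort_param(sprintf("`%s` must be > %s (got %s).", name, strict_min, x))
  }
  if (x < min) {
    abort_param(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  invisible(x)
}
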