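# Internal helpers: argument checks and reproducible sub-stream seeding.

stop_data <- function(..., class = "puffyield_data_error") {
  stop(errorCondition(paste0(...), class = c(class, "puffyield_error")))
}

stop_domain <- function(...) {
  stop_data(..., class = "puffyield_domain_error")
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  if (positive && x <= 0) stop_domain(name, " must be > 0, got ", x)
  if (non_negative && x < 0) stop_domain(name, " must be >= 0, got ", x)
  invisible(x)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, restoring
#' the caller's state afterwards.  With `seed = NULL` the expression runs on
#' the ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a component sub-stream seed from a root seed
#'
#' A single root seed fans out to deterministic per-component seeds so that
#' the design generator, the emissions simulator, the session renderer and
#' the observed-yield simulator can each be re-run independently while a
#' pipeline driven from one root seed remains bit-reproducible.
#'
#' @param root Integer root seed.
#' @param component Small non-negative integer counter identifying the
#'   consuming component.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, 1)
substream_seed <- function(root, component) {
  check_number(root, "root")
  check_number(component, "component", non_negative = TRUE)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; simple LCG-style mix
  s <- (as.double(root) %% m)
  s <- (s * 48271 + as.double(component) * 1299709 + 12345) %% m
  as.integer(s)
}
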