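`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package operations do not disturb the global random stream. A NULL
#' seed evaluates the code under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (integer && x != round(x)) stopf("'%s' must be an integer", name)
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

check_binary <- function(x, name = deparse(substitute(x))) {
  if (!all(x == 0 | x == 1)) stopf("'%s' must be strictly binary (0/1)", name)
  invisible(x)
}

#' Coerce input to a H x W x T stack array
#' @noRd
as_stack <- function(x, name = "stack") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stopf("'%s' must be a H x W x T array (frames on the third margin)", name)
  }
  if (prod(dim(x)) == 0L) stopf("'%s' is empty", name)
  storage.mode(x) <- "double"
  x
}
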