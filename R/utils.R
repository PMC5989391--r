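# Internal helpers: seeded RNG scoping, deterministic per-edge seeds,
# and stable log-determinants.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
.withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  code
}

#' Deterministic 31-bit polynomial string hash
#' @noRd
.stringHash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  h
}

#' Seed for one permutation test, keyed by master seed plus identifiers.
#'
#' Pair identifiers are sorted so the seed is invariant to argument order;
#' a tag separates MI from CMI streams. Keeps results independent of edge
#' iteration order and of variable ordering in the input matrix.
#' @noRd
.edgeSeed <- function(seed, tag, a, b, k = NULL) {
  key <- paste(c(tag, sort(c(a, b)), k), collapse = "\r")
  as.integer((.stringHash(key) + (seed %% 2147483647) * 7919) %% 2147483647)
}

#' Log-determinant via Cholesky with adaptive ridge fallback
#'
#' The plain matrix is factorized first; a ridge of 1e-8 * mean diagonal is
#' added only if that fails, so well-conditioned inputs are untouched.
#' @noRd
.logDet <- function(C, ids = NULL) {
  C <- as.matrix(C)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    eps <- 1e-8 * sum(diag(C)) / nrow(C)
    ch <- tryCatch(chol(C + diag(eps, nrow(C))), error = function(e) NULL)
    if (is.null(ch)) {
      stop("degenerate input: covariance/correlation matrix is singular",
           if (!is.null(ids)) paste0(" (variables: ",
                                     paste(ids, collapse = ", "), ")") else "",
           call. = FALSE)
    }
  }
  2 * sum(log(diag(ch)))
}

#' Check a numeric vector is a usable variable (finite, non-constant)
#' @noRd
.checkVariable <- function(x, id = "variable") {
  if (!is.numeric(x)) stop(id, " is not numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(id, " contains missing or non-finite values", call. = FALSE)
  if (length(x) < 3L) stop(id, " has fewer than 3 samples", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate input: ", id, " is constant", call. = FALSE)
  invisible(TRUE)
}
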