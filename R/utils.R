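#' @useDynLib speckleflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x == lower) || x > upper)
    stopf("`%s` = %g is outside %s%g, %g]", name, x,
          if (strict_lower) "(" else "[", lower, upper)
  invisible(x)
}

#' Derive a reproducible child seed from a master seed and a key
#'
#' A stable FNV-1a style hash of `(master_seed, ...)`, reduced to a
#' 31-bit integer, so that per-video and per-stage seeds do not depend on
#' the order in which items are generated.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/numeric key components (stage name, video id, ...).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed, scientific = FALSE), ...), collapse = "/")
  h <- 2166136261 %% 2147483648
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483645) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
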