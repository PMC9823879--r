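#' @keywords internal
"_PACKAGE"

#' Run code with a temporary, isolated RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous state so package internals
#' never perturb user-level random streams.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Round half away from zero to a fixed number of decimals
#'
#' Reported percentage metrics use conventional half-up rounding rather
#' than R's banker's rounding, so printed tables are reproduced digit for
#' digit.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a grayscale image object
#'
#' A `gray_image` is a numeric matrix with 8-bit intensity semantics
#' (values in \[0, 255\]) plus an optional logical brain mask of the same
#' shape.
#'
#' @param pixels numeric matrix, values in \[0, 255\].
#' @param brain_mask optional logical matrix, same dimensions as `pixels`.
#' @return a `gray_image` object.
#' @export
gray_image <- function(pixels, brain_mask = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  if (!is.null(brain_mask)) {
    brain_mask <- as.matrix(brain_mask)
    if (!identical(dim(brain_mask), dim(pixels))) {
      stop("brain_mask shape must equal pixel shape")
    }
    storage.mode(brain_mask) <- "logical"
  }
  structure(list(pixels = pixels, brain_mask = brain_mask),
            class = "gray_image")
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image %dx%d, range [%.1f, %.1f]%s>\n",
              d[1], d[2], min(x$pixels), max(x$pixels),
              if (is.null(x$brain_mask)) "" else
                sprintf(", mask %d px", sum(x$brain_mask))))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# 32-bit helpers for seed hashing (doubles hold exact integers < 2^53)
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

mul32 <- function(a, b) {
  (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
}

# splitmix32 finalizer: decorrelates structured seed inputs
mix32 <- function(x) {
  x <- (x + 2654435769) %% 4294967296
  x <- xor32(x, x %/% 65536)
  x <- mul32(x, 569420461)
  x <- xor32(x, x %/% 32768)
  x <- mul32(x, 1935289751)
  xor32(x, x %/% 32768)
}

#' Derive an independent child seed from structured inputs
#'
#' Hashes (seed, stream components) through a 32-bit mixing finalizer so
#' that arithmetically related inputs (consecutive indices, class
#' offsets) yield statistically unrelated RNG streams.  Plain linear
#' seed offsets leave detectable correlations between Mersenne--Twister
#' streams, which texture statistics are sensitive enough to pick up.
#'
#' @param seed master seed.
#' @param ... integer stream components (e.g. slice index, class code).
#' @return integer seed in 1..2147483645.
#' @export
derive_seed <- function(seed, ...) {
  x <- mix32(as.numeric(seed) %% 4294967296)
  for (k in c(...)) {
    x <- mix32(xor32(x, as.numeric(k) %% 4294967296))
  }
  as.integer(x %% 2147483645 + 1)
}

#' Hash a configuration object for run manifests
#' @param x any R object.
#' @return a short hash string.
#' @keywords internal
config_hash <- function(x) rlang::hash(x)
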