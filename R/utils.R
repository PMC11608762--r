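#' @keywords internal
"_PACKAGE"

#' @useDynLib scmbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp quantile rbeta runif sd setNames pbeta qchisq dist
#' @importFrom utils read.csv write.csv read.table write.table head
NULL

# Evaluate `expr` under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-item seed from an ensemble seed; kept below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index)) %% 2147483040L)
}

# Validate an 8-bit grayscale image stored as an integer matrix.
assert_image <- function(image, size = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(size) && !all(dim(image) == size)) {
    stop(sprintf("image must be %dx%d, got %dx%d",
                 size[1], size[2], nrow(image), ncol(image)), call. = FALSE)
  }
  if (any(image < 0 | image > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

# Most frequent value of an integer vector (lowest wins ties).
modal_value <- function(x) {
  tb <- tabulate(x + 1L)
  which.max(tb) - 1L
}

# Largest-remainder allocation of n items into proportions `w` (sums to n).
largest_remainder <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
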