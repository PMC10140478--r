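#' Derive a reproducible sub-seed from a parent seed and a label
#'
#' All stochastic operations in the package draw their own seed from a single
#' user-supplied integer via this fan-out, so that stages are reproducible
#' independently of how many random draws other stages consume.
#'
#' @param seed parent integer seed.
#' @param label character label naming the operation or sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  codes <- utf8ToInt(paste(label, collapse = "/"))
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) + h * 2654435) %% (2^31 - 2))
}

## internal: stop unless x is a single number in [lo, hi]
check_fraction <- function(x, name, lo = 0, hi = 1, strict_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= lo &&
    (if (strict_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in [%g, %g%s", name, lo, hi,
                 if (strict_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

## internal: central-difference Hessian of f at x
num_hessian <- function(f, x, eps = 1e-5) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  h <- pmax(abs(x), 1) * eps
  for (i in seq_len(p)) {
    for (j in i:p) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

## internal: average ranks
avg_rank <- function(x) rank(x, ties.method = "average", na.last = "keep")
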