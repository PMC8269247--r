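# Shared small helpers. Nothing here is exported.

#' @noRd
wrap_hour <- function(h) h %% 24

# sdlog such that a lognormal multiplicative factor has the requested CV
#' @noRd
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

# n multiplicative lognormal factors with mean 1 and coefficient of variation cv
#' @noRd
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in '%s'", name), call. = FALSE)
  invisible(x)
}

# relative standard deviation; NA-safe, 0/0 -> NA
#' @noRd
rsd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / abs(m)
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used only to
# fingerprint the parameter block in run manifests.
#' @noRd
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256); avoids 32-bit integer overflow
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by 16777619, done in two 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
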