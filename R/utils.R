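# internal helpers shared across modules

# run expr with a local RNG state; NULL seed uses the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# derive a child seed from a parent seed and a stream label, staying < 2^31
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1103L + as.integer(h %% 100000L)) %% 2147483629L
}

abort_arg <- function(...) stop(paste0(...), call. = FALSE)

#' Fisher z-transform with clipping
#'
#' Variance-stabilizing transform `atanh(r)` applied after clipping `|r|`
#' at `1 - clip` so perfect correlations stay finite and averageable.
#'
#' @param r numeric vector of correlations.
#' @param clip distance kept from `|r| = 1` before `atanh`.
#' @return numeric vector of z-values.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  r <- pmin(pmax(r, -1 + clip), 1 - clip)
  atanh(r)
}

# MATLAB filloutliers-style scaled MAD (Gaussian-consistent)
MAD_SCALE <- 1.4826

# replace flagged samples by linear interpolation from unflagged neighbours
interp_replace <- function(x, bad) {
  if (!any(bad)) return(x)
  if (all(bad)) abort_arg("all samples flagged as outliers")
  idx <- seq_along(x)
  x[bad] <- approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
  x
}

# column z-score using non-missing entries; constant columns -> 0
zscore_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd, na.rm = TRUE)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(x = out, center = center, scale = scale)
}
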