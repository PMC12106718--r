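# shared fixtures, generated in code and cached across test files

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# small default cohort reused by several files
small_cohort <- function() {
  cached_cohort("small", generate_cohort(
    24, 40, 300, n_runs = 1, keep_traces = FALSE, seed = 101))
}

# a smooth low-frequency series for lag tests
smooth_series <- function(n, seed) {
  withr::with_seed(seed, {
    x <- stats::filter(rnorm(n + 60), rep(1 / 15, 15), sides = 2)
    as.numeric(scale(x[31:(30 + n)]))
  })
}

# from-scratch two-way ANOVA mean squares for one n x 2 table (loop
# implementation, independent of the vectorized production path)
anova_oracle <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  grand <- mean(tab)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(tab[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(tab[, j]) - grand)^2
  sst <- sum((tab - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# latent-level null blocks with family random effects, x independent of y
null_family_blocks <- function(n, k, fam, family_effect = 0.3) {
  fi <- match(fam, unique(fam))
  nf <- length(unique(fam))
  mk <- function() sqrt(family_effect) * matrix(rnorm(nf * k), nf)[fi, ] +
    sqrt(1 - family_effect) * matrix(rnorm(n * k), n)
  list(x = mk(), y = mk())
}
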