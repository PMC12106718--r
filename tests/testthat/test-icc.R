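test_that("ICC variants match a from-scratch ANOVA oracle", {
  withr::with_seed(21, {
    n <- 200
    a <- matrix(rnorm(n * 8), n) + rnorm(n)  # shared row effects
    b <- a * 0.8 + matrix(rnorm(n * 8, sd = 0.5), n)
  })
  maps <- lapply(c("paper", "icc_c1", "icc_a1"),
                 function(v) icc_two_way(a, b, variant = v))
  names(maps) <- c("paper", "icc_c1", "icc_a1")
  for (j in seq_len(8)) {
    ms <- anova_oracle(cbind(a[, j], b[, j]))
    vr <- max(ms$msr - ms$mse, 0)
    expect_equal(maps$paper$table$icc[j], vr / (vr + ms$mse),
                 tolerance = 1e-12)
    expect_equal(maps$icc_c1$table$icc[j],
                 (ms$msr - ms$mse) / (ms$msr + ms$mse),
                 tolerance = 1e-12)
    expect_equal(maps$icc_a1$table$icc[j],
                 (ms$msr - ms$mse) /
                   (ms$msr + ms$mse + 2 / 200 * (ms$msc - ms$mse)),
                 tolerance = 1e-12)
  }
})

test_that("perfect agreement gives ICC 1 and tiny tables error", {
  withr::with_seed(22, a <- matrix(rnorm(40), 10))
  m <- icc_two_way(a, a)
  expect_equal(m$table$icc, rep(1, 4), tolerance = 1e-12)
  expect_error(icc_two_way(a[1:2, ], a[1:2, ]), "3 participants")
  expect_error(icc_two_way(a, a[, 1:2]), "identical dimensions")
})

test_that("independent measures give ICC near zero at large n", {
  withr::with_seed(23, {
    a <- matrix(rnorm(10000 * 30), 10000)
    b <- matrix(rnorm(10000 * 30), 10000)
  })
  expect_lt(abs(mean(icc_two_way(a, b)$table$icc)), 0.02)
})

test_that("the row-variance form reduces to (MSR - MSE) / MSR", {
  withr::with_seed(24, {
    a <- matrix(rnorm(50 * 20), 50) + 0.8 * rnorm(50)
    b <- a + matrix(rnorm(50 * 20, sd = 0.6), 50)
  })
  m <- icc_two_way(a, b)
  pos <- m$table$var_rows > 0
  expect_true(any(pos))
  expect_equal(m$table$icc[pos],
               ((m$table$msr - m$table$var_error) / m$table$msr)[pos],
               tolerance = 1e-12)
})

test_that("ICC is invariant to a common affine transform", {
  withr::with_seed(25, {
    a <- matrix(rnorm(60 * 10), 60) + rnorm(60)
    b <- a + matrix(rnorm(60 * 10, sd = 0.4), 60)
  })
  for (v in c("paper", "icc_c1", "icc_a1"))
    expect_equal(icc_two_way(3.2 * a - 7, 3.2 * b - 7, variant = v)$table$icc,
                 icc_two_way(a, b, variant = v)$table$icc,
                 tolerance = 1e-9)
})

test_that("added noise on one measure lowers expected ICC", {
  withr::with_seed(26, {
    diffs <- replicate(200, {
      row_eff <- rnorm(30)
      a <- row_eff + rnorm(30, sd = 0.5)
      b <- row_eff + rnorm(30, sd = 0.5)
      clean <- icc_two_way(cbind(a), cbind(b))$table$icc
      noisy <- icc_two_way(cbind(a), cbind(b + rnorm(30)))$table$icc
      clean - noisy
    })
  })
  expect_gt(mean(diffs), 0)
})

test_that("multi-session input averages per-session ICC", {
  withr::with_seed(27, {
    mk <- function() {
      a <- matrix(rnorm(40 * 6), 40) + rnorm(40)
      list(a = a, b = a + matrix(rnorm(40 * 6, sd = 0.5), 40))
    }
    s1 <- mk()
    s2 <- mk()
  })
  avg <- icc_two_way(list(s1$a, s2$a), list(s1$b, s2$b))
  expect_equal(avg$table$icc,
               (icc_two_way(s1$a, s1$b)$table$icc +
                  icc_two_way(s2$a, s2$b)$table$icc) / 2,
               tolerance = 1e-12)
  expect_equal(avg$n_sessions, 2L)
})

test_that("network comparison separates distinct ICC distributions", {
  atlas <- tibble::tibble(roi = paste0("roi_", 1:60),
                          network = rep(c("A", "B", "C"), each = 20))
  icc <- structure(list(
    table = tibble::tibble(roi = atlas$roi,
                           icc = c(runif(20, 0.05, 0.15),
                                   runif(20, 0.45, 0.55),
                                   runif(20, 0.85, 0.95)),
                           var_rows = 1, var_error = 1, msr = 1,
                           msc = 1),
    variant = "paper", n_participants = 50, n_sessions = 1L),
    class = "icc_map")
  ns <- network_icc_summary(icc, atlas)
  expect_lt(ns$p_value, 1e-6)

  # H statistic matches the rank-sum formula on an untied toy
  icc$table$icc <- (1:60) / 100
  ns2 <- network_icc_summary(icc, atlas)
  ranks <- rank(fisher_z(icc$table$icc))
  groups <- split(ranks, atlas$network)
  n_tot <- 60
  h_oracle <- 12 / (n_tot * (n_tot + 1)) *
    sum(vapply(groups, function(g)
      length(g) * (mean(g) - (n_tot + 1) / 2)^2, numeric(1)))
  expect_equal(ns2$kruskal_h, h_oracle, tolerance = 1e-10)

  # a network with one ROI is excluded with a warning
  atlas2 <- atlas
  atlas2$network[60] <- "Tiny"
  expect_warning(network_icc_summary(icc, atlas2), "< 2 ROIs")
})

test_that("network test is calibrated under a common null", {
  withr::with_seed(28, {
    atlas <- tibble::tibble(roi = paste0("roi_", 1:90),
                            network = rep(c("A", "B", "C"), each = 30))
    pvals <- replicate(1000, {
      icc <- structure(list(
        table = tibble::tibble(roi = atlas$roi,
                               icc = runif(90, 0.2, 0.8),
                               var_rows = 1, var_error = 1, msr = 1,
                               msc = 1),
        variant = "paper", n_participants = 50, n_sessions = 1L),
        class = "icc_map")
      network_icc_summary(icc, atlas)$p_value
    })
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
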