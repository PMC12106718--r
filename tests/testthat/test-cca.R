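test_that("CCA reduces to |Pearson r| in one dimension and matches the
           reference implementation", {
  withr::with_seed(41, {
    x <- rnorm(200)
    y <- 0.6 * x + rnorm(200)
  })
  fit <- fit_cca(cbind(x), cbind(y))
  expect_equal(fit$cor[1], abs(cor(x, y)), tolerance = 1e-12)

  withr::with_seed(42, {
    bx <- matrix(rnorm(150 * 6), 150)
    by <- matrix(rnorm(150 * 4), 150)
  })
  fit2 <- fit_cca(bx, by)
  oracle <- stats::cancor(bx, by)
  expect_equal(fit2$cor, oracle$cor, tolerance = 1e-10)
  # score correlations equal the canonical correlations
  for (m in seq_along(fit2$cor))
    expect_equal(cor(fit2$xscores[, m], fit2$yscores[, m]),
                 fit2$cor[m], tolerance = 1e-9)
})

test_that("CCA is invariant to invertible within-block transforms", {
  withr::with_seed(43, {
    bx <- matrix(rnorm(120 * 5), 120)
    by <- matrix(rnorm(120 * 5), 120)
    amat <- matrix(rnorm(25), 5) + diag(5)
  })
  base <- fit_cca(bx, by)$cor
  expect_equal(fit_cca(bx %*% amat, by)$cor, base, tolerance = 1e-8)
  # y an invertible transform of x: every mode is perfect
  fit_id <- fit_cca(bx, bx %*% amat)
  expect_equal(fit_id$cor, rep(1, 5), tolerance = 1e-9)
  expect_error(fit_cca(cbind(bx, bx[, 1]), by), "rank deficient")
})

test_that("family permutations keep families together", {
  fam <- c("a", "a", "b", "c", "c", "d", "e", "e", "e", "f")
  withr::with_seed(44, {
    for (i in 1:25) {
      p <- family_permutation(fam)
      expect_setequal(p, 1:10)
      # each family's slots receive a same-size family, members in order
      for (f in unique(fam)) {
        slots <- which(fam == f)
        src <- p[slots]
        expect_equal(length(unique(fam[src])), 1L)
        expect_equal(length(src), sum(fam == fam[src[1]]))
        expect_true(all(diff(src) > 0))
      }
    }
    # all singletons: unrestricted shuffle of everything
    p1 <- family_permutation(as.character(1:8))
    expect_setequal(p1, 1:8)
  })
  expect_warning(family_permutation(c("a", "a", "b", "c", "c", "c")),
                 "unrestricted")
})

test_that("mode permutation test hits the add-one floor and detects a
           planted mode", {
  withr::with_seed(45, {
    lat <- rnorm(150)
    bx <- matrix(rnorm(150 * 3), 150) + lat
    by <- matrix(rnorm(150 * 3), 150) + lat
  })
  fam <- rep(sprintf("f%d", 1:75), each = 2)
  pt <- permutation_test_modes(bx, by, fam, n_perm = 99, seed = 2)
  expect_equal(pt$table$perm_p[1], 1 / 100)  # stronger than every null
  expect_true(pt$table$significant[1])
})

test_that("null permutation p-values are uniform", {
  fam <- sprintf("f%02d", rep(1:40, each = 2))
  withr::with_seed(46, {
    pvals <- vapply(1:500, function(s) {
      d <- null_family_blocks(80, 3, fam)
      permutation_test_modes(d$x, d$y, fam, n_perm = 200,
                             seed = 500 + s)$table$perm_p[1]
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("back-projection recovers self-correlations and controls FWER", {
  withr::with_seed(47, {
    score <- rnorm(120)
    vars <- cbind(self = score,
                  matrix(rnorm(120 * 9), 120,
                         dimnames = list(NULL, paste0("n", 1:9))))
  })
  fam <- sprintf("f%02d", rep(1:60, each = 2))
  bp <- backproject_weights(score, vars, fam, n_perm = 500, seed = 3)
  expect_equal(bp$table$weight[1], 1, tolerance = 1e-9)
  expect_true(bp$table$significant[1])

  # pure-noise variables: at most one of 20 repeats shows any hit
  withr::with_seed(48, {
    hits <- vapply(1:20, function(r) {
      s <- rnorm(100)
      noise <- matrix(rnorm(100 * 50), 100)
      b <- backproject_weights(s, noise, sprintf("f%02d", rep(1:50, 2)),
                               n_perm = 1000, alpha = 0.001,
                               seed = 900 + r)
      sum(b$table$significant)
    }, numeric(1))
  })
  expect_lte(sum(hits > 0), 1)

  # constant variables are excluded with a report
  vars2 <- cbind(vars, flat = rep(2, 120))
  bp2 <- backproject_weights(score, vars2, fam, n_perm = 200, seed = 5)
  expect_equal(bp2$excluded, "flat")
})

test_that("1-D back-projected weight equals the cross-block correlation", {
  withr::with_seed(49, {
    x <- rnorm(300)
    y <- 0.5 * x + rnorm(300)
  })
  fit <- fit_cca(cbind(x), cbind(y))
  fam <- as.character(1:300)
  suppressWarnings(
    bp <- backproject_weights(fit$yscores[, 1], cbind(xvar = x), fam,
                              n_perm = 100, seed = 6))
  expect_equal(abs(bp$table$weight[1]), abs(cor(x, y)),
               tolerance = 1e-9)
})

test_that("sign alignment is an involution that preserves correlations", {
  withr::with_seed(50, {
    bx <- matrix(rnorm(80 * 3), 80)
    by <- matrix(rnorm(80 * 3), 80)
  })
  fam <- as.character(rep(1:40, 2))
  fit <- fit_cca(bx, by)
  colnames(by) <- paste0("v", 1:3)
  bp_beh <- backproject_weights(fit$yscores[, 1], by, fam,
                                n_perm = 100, seed = 7)
  bp_br <- backproject_weights(fit$xscores[, 1], bx, fam,
                               n_perm = 100, seed = 8)
  anchor <- bp_beh$table$variable[which.max(abs(bp_beh$table$weight))]
  want <- if (bp_beh$table$weight[bp_beh$table$variable == anchor] > 0)
    "negative" else "positive"
  al <- align_signs(fit, bp_beh, bp_br, anchor = anchor,
                    desired_sign = want)
  expect_true(al$flipped)
  expect_equal(al$fit$cor, fit$cor)
  expect_equal(al$fit$xscores[, 1], -fit$xscores[, 1])
  expect_equal(cor(al$fit$xscores[, 1], al$fit$yscores[, 1]),
               fit$cor[1], tolerance = 1e-9)
  # applying it again restores the original state
  back <- align_signs(al$fit, al$behavior_backproj, al$brain_backproj,
                      anchor = anchor,
                      desired_sign = setdiff(c("negative", "positive"),
                                             want))
  expect_equal(back$fit$xscores, fit$xscores)
  expect_warning(align_signs(fit, bp_beh, bp_br, anchor = "absent",
                             desired_sign = "negative"),
                 "not found")
})

test_that("mode similarity returns the four expected correlations", {
  withr::with_seed(51, {
    a <- list(behavior_scores = rnorm(100), topo_scores = rnorm(100),
              behavior_weights = rnorm(40), topo_weights = rnorm(60))
  })
  same <- compare_modes(a, a)
  expect_equal(same$r, rep(1, 4))
  flipped <- lapply(a, function(v) -v)
  expect_equal(compare_modes(a, flipped)$r, rep(-1, 4))
  withr::with_seed(52, {
    b <- list(behavior_scores = rnorm(100), topo_scores = rnorm(100),
              behavior_weights = rnorm(40), topo_weights = rnorm(60))
  })
  expect_true(all(abs(compare_modes(a, b)$r) < 0.3))
  b$topo_weights <- rnorm(10)
  expect_error(compare_modes(a, b), "mismatched")
})

test_that("map-space regression removes exactly the shared pattern", {
  withr::with_seed(53, {
    reg <- matrix(rnorm(20 * 50), 20)
    map2 <- matrix(rnorm(20 * 50), 20)
    target <- 0.6 * reg + map2
  })
  resid <- regress_out_map(target, reg)
  for (i in 1:20)
    expect_gt(cor(resid[i, ], map2[i, ]), 0.95)
  expect_lt(max(abs(regress_out_map(reg, reg))), 1e-10)
  # orthogonal maps: unchanged up to mean removal
  orth_t <- matrix(rep(c(1, -1), 25), 1)
  orth_r <- matrix(rep(c(1, 1, -1, -1), length.out = 50), 1)
  out <- regress_out_map(orth_t, orth_r)
  expect_equal(as.numeric(out), as.numeric(orth_t - mean(orth_t)),
               tolerance = 1e-10)
  expect_error(regress_out_map(target, matrix(1, 20, 50)), "constant")
})

test_that("time-domain regression handles lags and does not overfit", {
  x <- smooth_series(500, 54)
  fs <- frame_series(x, 0.72, "GS")
  resid0 <- regress_out_series(fs, fs)
  expect_lt(max(abs(resid0$values)), 1e-10)

  # white-noise regressor removes about 1/n of the variance, no more
  withr::with_seed(55, wn <- rnorm(500))
  resid1 <- regress_out_series(fs, wn)
  expect_lt(1 - var(resid1$values) / var(x), 0.01)

  # lagged flipped regressor removes a planted component
  base <- smooth_series(516, 56)
  rvt <- base[17:516]
  gs_planted <- smooth_series(500, 57) - 0.8 * base[1:500]
  # gs at frame t contains -rvt(t - 16)
  res <- regress_out_series(frame_series(gs_planted, 0.72, "GS"),
                            frame_series(rvt, 0.72, "RVT"),
                            lag_frames = 16, flip = TRUE)
  expect_equal(attr(res, "frame_offset"), 16)
  planted <- -0.8 * base[1:500]
  expect_lt(abs(cor(res$values, planted[17:500])),
            abs(cor(gs_planted[17:500], planted[17:500])))
  expect_error(regress_out_series(fs, list(wn, wn)), "collinear")
})
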