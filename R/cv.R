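# Family-aware 10-fold cross-validation of the CCA: out-of-sample
# canonical correlations, permutation significance with an any-fold
# Bonferroni rule, and weight-stability metrics.

#' Family-aware fold assignment
#'
#' Partitions participants into `k` folds, keeping every family — and in
#' particular every monozygotic twin pair — entirely inside one fold.
#' Families are shuffled (seeded), ordered by decreasing size, and each
#' assigned greedily to the currently smallest fold, so fold sizes differ
#' by at most the largest family size. Deterministic given the seed.
#'
#' @param family tibble with `participant` and `family_id` columns (a
#'   `physiocca_cohort$family` table works directly).
#' @param k number of folds.
#' @param seed integer seed.
#' @return A `fold_plan`: tibble (`participant`, `family_id`, `fold`)
#'   plus `k` and `seed`.
#' @export
family_aware_folds <- function(family, k = 10, seed = 1) {
  family <- tibble::as_tibble(family)
  if (!all(c("participant", "family_id") %in% names(family)))
    abort_arg("family needs participant and family_id columns")
  n <- nrow(family)
  if (n < 2 * k) abort_arg("need at least 2k participants")
  sizes <- table(family$family_id)
  if (max(sizes) > n / k)
    abort_arg("a family is larger than n / k; reduce k")
  assign <- with_seed(seed, {
    fams <- sample(names(sizes))
    fams <- fams[order(-sizes[fams])]
    fold_sizes <- integer(k)
    fold_of <- setNames(integer(length(fams)), fams)
    for (f in fams) {
      tgt <- which.min(fold_sizes)
      fold_of[f] <- tgt
      fold_sizes[tgt] <- fold_sizes[tgt] + sizes[[f]]
    }
    fold_of
  })
  out <- family[c("participant", "family_id")]
  out$fold <- unname(assign[out$family_id])
  structure(list(table = out, k = k, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d participants in %d folds (sizes %s)>\n",
              nrow(x$table), x$k,
              paste(table(x$table$fold), collapse = ", ")))
  invisible(x)
}

# sign-align weight vectors to the first split, then mean pairwise r
weight_stability <- function(wmat) {
  k <- ncol(wmat)
  for (j in seq_len(k)[-1])
    if (cor(wmat[, 1], wmat[, j]) < 0) wmat[, j] <- -wmat[, j]
  cc <- cor(wmat)
  mean(cc[upper.tri(cc)])
}

#' Cross-validated CCA
#'
#' For each fold: fits the component reductions
#' ([topography_components()], [behavioral_components()] after
#' standardization) and the CCA on the training participants only,
#' projects the held-out participants through the training bases and
#' canonical weights, and records the Pearson correlation of the
#' test-side mode-1 canonical score pair (the out-of-sample canonical
#' correlation). Weight stability is the mean pairwise correlation, after
#' sign alignment to the first split, of the full-length training weights
#' (training canonical scores correlated with the original variables —
#' the representation that is comparable across splits, since each
#' split's component basis differs).
#'
#' @param topos participants x ROI matrix (complete).
#' @param behavior participants x measures matrix or tibble with a
#'   `participant` column (missing allowed).
#' @param plan a [family_aware_folds()] plan covering the participants.
#' @param k_components components per block.
#' @param confounds optional participants x c confound matrix applied to
#'   both blocks (fitted on training rows only).
#' @return A `cv_report`: per-fold tibble (`fold`, `n_test`, `oos_r`),
#'   `mean_oos_r`, `weight_stability_brain` / `_behavior`, `best_fold`,
#'   and the stored per-fold fits needed by
#'   [cv_permutation_significance()].
#' @export
cross_validate_cca <- function(topos, behavior, plan, k_components = 20,
                               confounds = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  topos <- as.matrix(topos)
  if (is.data.frame(behavior)) behavior <- behavior_matrix(behavior)
  behavior <- as.matrix(behavior)
  roster <- plan$table$participant
  if (!is.null(rownames(topos)) && !is.null(rownames(behavior)) &&
      all(roster %in% rownames(topos)) &&
      all(roster %in% rownames(behavior))) {
    topos <- topos[roster, , drop = FALSE]
    behavior <- behavior[roster, , drop = FALSE]
  }
  n <- nrow(topos)
  if (nrow(behavior) != n) abort_arg("blocks must share participants")
  folds <- plan$table$fold
  fold_fits <- vector("list", plan$k)
  per_fold <- numeric(plan$k)
  wb_brain <- NULL
  wb_beh <- NULL
  for (f in seq_len(plan$k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(te) < 3) abort_arg("test fold ", f, " smaller than 3")
    conf_tr <- if (!is.null(confounds)) confounds[tr, , drop = FALSE]
    # training-side fits only
    topo_cs <- topography_components(topos[tr, , drop = FALSE],
                                     k = k_components,
                                     confounds = conf_tr)
    zb <- zscore_cols(behavior[tr, , drop = FALSE])
    beh_tr <- if (is.null(confounds)) zb$x else deconfound(zb$x, conf_tr)
    beh_cs <- behavioral_components(beh_tr, k = k_components)
    fit <- fit_cca(topo_cs, beh_cs)
    # project held-out participants through the training bases
    beh_te <- sweep(sweep(behavior[te, , drop = FALSE], 2, zb$center),
                    2, zb$scale, "/")
    if (!is.null(confounds)) {
      # residualize test rows with training-fitted coefficients
      beh_te <- residualize_with(beh_te, zb$x, conf_tr,
                                 confounds[te, , drop = FALSE])
    }
    x_te <- predict(topo_cs, topos[te, , drop = FALSE])
    y_te <- predict(beh_cs, beh_te)
    xs <- sweep(x_te, 2, fit$xcenter) %*% fit$xcoef[, 1]
    ys <- sweep(y_te, 2, fit$ycenter) %*% fit$ycoef[, 1]
    per_fold[f] <- cor(xs, ys)
    # full-length training weights, comparable across splits
    wb_brain <- cbind(wb_brain,
                      as.numeric(cor(fit$xscores[, 1],
                                     topos[tr, , drop = FALSE])))
    beh0 <- beh_tr
    beh0[is.na(beh0)] <- 0
    wb_beh <- cbind(wb_beh, as.numeric(cor(fit$yscores[, 1], beh0)))
    fold_fits[[f]] <- list(test = te, train = tr, fit = fit,
                           x_tr = topo_cs$scores, y_tr = beh_cs$scores,
                           x_te = x_te, y_te = y_te,
                           in_sample_r = fit$cor[1])
  }
  structure(list(
    table = tibble::tibble(fold = seq_len(plan$k),
                           n_test = as.integer(table(folds)),
                           oos_r = per_fold),
    mean_oos_r = mean(per_fold),
    weight_stability_brain = weight_stability(wb_brain),
    weight_stability_behavior = weight_stability(wb_beh),
    best_fold = which.max(per_fold), plan = plan,
    k_components = k_components, fold_fits = fold_fits,
    data = list(topos = topos, behavior = behavior,
                confounds = confounds)),
    class = "cv_report")
}

# one full-refit null draw: permute raw behavior training rows, rebuild
# standardization + reductions + CCA on train, score the intact test fold
cv_fold_oos_full <- function(report, f, perm) {
  ff <- report$fold_fits[[f]]
  tr <- ff$train
  te <- ff$test
  topos <- report$data$topos
  behavior <- report$data$behavior
  confounds <- report$data$confounds
  beh_perm <- behavior
  beh_perm[tr, ] <- behavior[tr[perm], ]
  conf_tr <- if (!is.null(confounds)) confounds[tr, , drop = FALSE]
  topo_cs <- topography_components(topos[tr, , drop = FALSE],
                                   k = report$k_components,
                                   confounds = conf_tr)
  zb <- zscore_cols(beh_perm[tr, , drop = FALSE])
  beh_tr <- if (is.null(confounds)) zb$x else deconfound(zb$x, conf_tr)
  beh_cs <- behavioral_components(beh_tr, k = report$k_components)
  fit <- fit_cca(topo_cs, beh_cs)
  beh_te <- sweep(sweep(beh_perm[te, , drop = FALSE], 2, zb$center), 2,
                  zb$scale, "/")
  if (!is.null(confounds))
    beh_te <- residualize_with(beh_te, zb$x, conf_tr,
                               confounds[te, , drop = FALSE])
  x_te <- predict(topo_cs, topos[te, , drop = FALSE])
  y_te <- predict(beh_cs, beh_te)
  cor(sweep(x_te, 2, fit$xcenter) %*% fit$xcoef[, 1],
      sweep(y_te, 2, fit$ycenter) %*% fit$ycoef[, 1])
}

# predict residuals for new rows from a training deconfounding fit
residualize_with <- function(new_z, train_z, conf_tr, conf_new) {
  out <- new_z
  design_tr <- cbind(1, conf_tr)
  design_new <- cbind(1, conf_new)
  for (j in seq_len(ncol(train_z))) {
    obs <- !is.na(train_z[, j])
    beta <- qr.coef(qr(design_tr[obs, , drop = FALSE]),
                    train_z[obs, j])
    beta[is.na(beta)] <- 0
    pred <- design_new %*% beta
    out[, j] <- new_z[, j] - pred
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report: %d folds, mean out-of-sample r = %.4f, ",
                     "stability brain %.3f / behavior %.3f>\n"),
              nrow(x$table), x$mean_oos_r, x$weight_stability_brain,
              x$weight_stability_behavior))
  invisible(x)
}

#' Permutation significance of the cross-validated CCA
#'
#' For each permutation, the behavioral rows of every fold's training
#' set are shuffled under family exchangeability blocks (the blocks are
#' whole within folds by construction), the training model is refit, and
#' the held-out fold is scored, yielding a null out-of-sample
#' correlation per fold and, averaging across folds within each
#' permutation, a null for the mean. By default (`refit = "cca"`) the
#' component reductions are held fixed and only the canonical weights
#' are refit on the permuted training component scores — the cost that
#' makes thousands of permutations practical; `refit = "full"` re-runs
#' the standardization and both component reductions on the permuted
#' raw behavior block as well. Per-fold and mean-level p-values use the
#' add-one correction; the Bonferroni-style decision rule rejects when
#' any fold's p falls below `alpha_fold` (0.005 for 10 folds).
#'
#' @param report a `cv_report` from [cross_validate_cca()].
#' @param n_perm permutations per fold.
#' @param seed integer seed.
#' @param alpha_fold per-fold significance threshold.
#' @param refit `"cca"` (reductions fixed) or `"full"`.
#' @return The `cv_report` with `perm` added: per-fold p-values,
#'   mean-level p, and the any-fold decision.
#' @export
cv_permutation_significance <- function(report, n_perm = 5000, seed = 1,
                                        alpha_fold = 0.005,
                                        refit = c("cca", "full")) {
  stopifnot(inherits(report, "cv_report"))
  refit <- match.arg(refit)
  if (n_perm < 100) warning("n_perm < 100: unstable p-value tails")
  plan <- report$plan
  fam_all <- plan$table$family_id
  k <- plan$k
  null_r <- matrix(NA_real_, n_perm, k)
  with_seed(child_seed(seed, "cvperm"), {
    for (f in seq_len(k)) {
      ff <- report$fold_fits[[f]]
      st <- family_perm_struct(fam_all[ff$train])
      if (refit == "full") {
        for (b in seq_len(n_perm))
          null_r[b, f] <- cv_fold_oos_full(report, f,
                                           draw_family_perm(st))
        next
      }
      wx <- whiten_block(ff$x_tr, label = "x block")
      wy <- whiten_block(ff$y_tr, label = "y block")
      fit <- ff$fit
      x_te_c <- sweep(ff$x_te, 2, fit$xcenter)
      y_te_c <- sweep(ff$y_te, 2, fit$ycenter)
      scale_n <- sqrt(nrow(ff$x_tr) - 1)
      for (b in seq_len(n_perm)) {
        perm <- draw_family_perm(st)
        s <- svd(crossprod(wx$u, wy$u[perm, , drop = FALSE]),
                 nu = 1, nv = 1)
        xcoef <- wx$w %*% s$u * scale_n
        ycoef <- wy$w %*% s$v * scale_n
        # the permuted training model is scored on the intact test fold
        null_r[b, f] <- cor(x_te_c %*% xcoef, y_te_c %*% ycoef)
      }
    }
  })
  obs <- report$table$oos_r
  p_fold <- vapply(seq_len(k), function(f)
    (1 + sum(null_r[, f] >= obs[f])) / (1 + n_perm), numeric(1))
  null_mean <- rowMeans(null_r)
  p_mean <- (1 + sum(null_mean >= report$mean_oos_r)) / (1 + n_perm)
  report$table$perm_p <- p_fold
  report$perm <- list(p_fold = p_fold, p_mean = p_mean,
                      any_fold_significant = any(p_fold < alpha_fold),
                      alpha_fold = alpha_fold, n_perm = n_perm,
                      null_mean = null_mean)
  report
}
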