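# Canonical correlation analysis with family-structure-respecting
# permutation inference, max-statistic FWER back-projection, sign
# alignment, mode comparison and the regress-out control analyses.

# SVD whitening of a centered block; rank-checked
whiten_block <- function(x, tol = 1e-10, label = "block") {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc)
  if (any(s$d < tol * s$d[1]))
    abort_arg(label, " is rank deficient; use fewer components (k)")
  list(u = s$u, w = s$v %*% diag(1 / s$d, length(s$d)), center = ctr)
}

#' Fit a canonical correlation analysis
#'
#' Finds paired linear combinations of two component blocks with maximal
#' correlation. Both blocks are centered and whitened by SVD; the
#' canonical structure is the SVD of the cross-product of the whitened
#' blocks, giving `min(kx, ky)` modes ordered by decreasing canonical
#' correlation. Canonical scores have unit variance, and the correlation
#' of each score pair equals the mode's canonical correlation.
#'
#' @param x,y participants x components matrices (same rows), or
#'   `component_scores` objects.
#' @return A `cca_fit`: canonical correlations `cor`, weight matrices
#'   `xcoef` / `ycoef` (original component space), per-participant score
#'   matrices `xscores` / `yscores`, centers and dimensions.
#' @export
fit_cca <- function(x, y) {
  if (inherits(x, "component_scores")) x <- x$scores
  if (inherits(y, "component_scores")) y <- y$scores
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort_arg("blocks must share participants")
  n <- nrow(x)
  if (n < 4) abort_arg("need at least 4 participants")
  wx <- whiten_block(x, label = "x block")
  wy <- whiten_block(y, label = "y block")
  k <- min(ncol(x), ncol(y))
  s <- svd(crossprod(wx$u, wy$u), nu = k, nv = k)
  r <- pmin(pmax(s$d[seq_len(k)], 0), 1)
  scale_n <- sqrt(n - 1)
  xcoef <- wx$w %*% s$u * scale_n
  ycoef <- wy$w %*% s$v * scale_n
  xs <- sweep(x, 2, wx$center) %*% xcoef
  ys <- sweep(y, 2, wy$center) %*% ycoef
  dimnames(xs) <- list(rownames(x), paste0("mode_", seq_len(k)))
  dimnames(ys) <- dimnames(xs)
  structure(list(cor = r, xcoef = xcoef, ycoef = ycoef,
                 xcenter = wx$center, ycenter = wy$center,
                 xscores = xs, yscores = ys, n = n,
                 k = c(x = ncol(x), y = ncol(y))),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit: %d modes, n = %d, first canonical r = %.4f>\n",
              length(x$cor), x$n, x$cor[1]))
  invisible(x)
}

# ---- family-blocked permutation -------------------------------------

normalize_family <- function(family, n, rownames_hint = NULL) {
  if (is.data.frame(family)) {
    if (!all(c("participant", "family_id") %in% names(family)))
      abort_arg("family table needs participant and family_id columns")
    ids <- family$family_id
    if (!is.null(rownames_hint) &&
        all(rownames_hint %in% family$participant))
      ids <- family$family_id[match(rownames_hint, family$participant)]
    if (length(ids) != n) abort_arg("family table does not match rows")
    return(as.character(ids))
  }
  if (length(family) != n) abort_arg("family vector does not match rows")
  as.character(family)
}

#' Family-respecting permutation of participant order
#'
#' Draws one restricted permutation: whole families are exchanged only
#' among families of identical size, and the order of members within a
#' family is fixed. Participants in one-member families therefore permute
#' freely among themselves, and the scheme reduces to an unrestricted
#' permutation when everyone is a singleton. If no two families share a
#' size, the permutation falls back to unrestricted with a warning.
#'
#' @param family character vector of family IDs, one per participant, or
#'   a tibble with `participant` / `family_id` columns.
#' @return Integer index vector `perm` such that row `i` of the permuted
#'   block is row `perm[i]` of the original.
#' @export
family_permutation <- function(family) {
  st <- family_perm_struct(as.character(family))
  draw_family_perm(st)
}

# precompute the exchangeability blocks: one position matrix (size x
# n_families) per family-size class, so each draw is vectorized
family_perm_struct <- function(fam) {
  n <- length(fam)
  members <- split(seq_len(n), fam)
  sizes <- lengths(members)
  unrestricted <- all(table(sizes) == 1) && length(members) > 1
  if (unrestricted)
    warning("no two families of equal size; unrestricted permutation")
  classes <- lapply(unique(sizes), function(s) {
    block <- members[sizes == s]
    if (length(block) < 2) return(NULL)
    matrix(unlist(block, use.names = FALSE), nrow = s)
  })
  classes <- classes[!vapply(classes, is.null, logical(1))]
  list(n = n, classes = classes, unrestricted = unrestricted)
}

draw_family_perm <- function(st) {
  if (st$unrestricted) return(sample.int(st$n))
  perm <- seq_len(st$n)
  for (cl in st$classes) {
    sh <- sample.int(ncol(cl))
    perm[as.vector(cl)] <- as.vector(cl[, sh, drop = FALSE])
  }
  perm
}

#' Permutation test of CCA mode significance
#'
#' Estimates each mode's significance by permuting the participant order
#' of one block under family exchangeability blocks and refitting the
#' CCA. Every permutation records the first (largest) canonical
#' correlation, building a null of maxima; the p-value of mode `m` is
#' the add-one-corrected fraction of null maxima at or above the observed
#' `r_m`, and a mode is declared significant when the observed value
#' exceeds the 95th percentile of the null (p < 0.05).
#'
#' Whitening is computed once: permuting rows changes neither a block's
#' column means nor its covariance, so each permutation only needs the
#' cross-product of the permuted whitened block with the other.
#'
#' @param x,y participants x components blocks (or `component_scores`).
#' @param family family IDs per participant (vector or tibble).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha significance level for the percentile criterion.
#' @return A `cca_perm_test`: tibble (`mode`, `canonical_r`, `perm_p`,
#'   `significant`), the null maxima vector, and the fitted `cca_fit`.
#' @export
permutation_test_modes <- function(x, y, family, n_perm = 5000,
                                   seed = 1, alpha = 0.05) {
  if (inherits(x, "component_scores")) x <- x$scores
  if (inherits(y, "component_scores")) y <- y$scores
  x <- as.matrix(x)
  y <- as.matrix(y)
  fam <- normalize_family(family, nrow(x), rownames(x))
  fit <- fit_cca(x, y)
  wx <- whiten_block(x, label = "x block")
  wy <- whiten_block(y, label = "y block")
  st <- family_perm_struct(fam)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- draw_family_perm(st)
      max(svd(crossprod(wx$u[perm, , drop = FALSE], wy$u))$d)
    }, numeric(1))
  })
  p <- vapply(fit$cor, function(r) (1 + sum(null_max >= r)) /
                (1 + n_perm), numeric(1))
  thr <- quantile(null_max, 1 - alpha, names = FALSE)
  structure(list(
    table = tibble::tibble(mode = seq_along(fit$cor),
                           canonical_r = fit$cor, perm_p = p,
                           significant = fit$cor > thr),
    null_max = null_max, threshold = thr, n_perm = n_perm,
    alpha = alpha, fit = fit), class = "cca_perm_test")
}

#' @export
print.cca_perm_test <- function(x, ...) {
  n_sig <- sum(x$table$significant)
  cat(sprintf("<cca_perm_test: %d permutations, %d significant mode(s)>\n",
              x$n_perm, n_sig))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Back-project canonical scores onto the original variables
#'
#' "Full-length" weights: the Pearson correlation of one mode's
#' participant scores with every original (pre-reduction) variable or
#' ROI, with family-wise error controlled by a max-statistic permutation
#' null — each permutation shuffles the scores under the family blocks
#' and records the maximum `|r|` across variables; observed weights
#' exceeding the `1 - alpha` quantile of that null are flagged
#' significant. Missing cells are mean-imputed (after standardization)
#' so the observed statistic and its null are computed identically;
#' constant variables are excluded with a report.
#'
#' @param scores numeric vector of one mode's participant scores.
#' @param originals participants x variables matrix (behavior or
#'   topographies).
#' @param family family IDs per participant.
#' @param n_perm number of permutations.
#' @param alpha FWER level.
#' @param seed integer seed.
#' @return A `backprojection`: tibble (`variable`, `weight`, `p_fwer`,
#'   `significant`), the null maxima and the excluded-variable report.
#' @export
backproject_weights <- function(scores, originals, family,
                                n_perm = 10000, alpha = 0.001, seed = 1) {
  s <- as.numeric(scores)
  m <- as.matrix(originals)
  if (length(s) != nrow(m)) abort_arg("scores must match participants")
  fam <- normalize_family(family, nrow(m), rownames(m))
  vars <- colnames(m) %||% paste0("var_", seq_len(ncol(m)))
  sds <- apply(m, 2, sd, na.rm = TRUE)
  constant <- !is.finite(sds) | sds == 0
  z <- zscore_cols(m[, !constant, drop = FALSE])$x
  z[is.na(z)] <- 0
  sz <- (s - mean(s)) / sd(s)
  n <- length(s)
  denom <- n - 1
  obs <- as.numeric(crossprod(z, sz)) / denom
  st <- family_perm_struct(fam)
  null_max <- with_seed(child_seed(seed, "backproject"), {
    vapply(seq_len(n_perm), function(b) {
      perm <- draw_family_perm(st)
      max(abs(crossprod(z, sz[perm])) / denom)
    }, numeric(1))
  })
  thr <- quantile(null_max, 1 - alpha, names = FALSE)
  p <- vapply(abs(obs), function(r) (1 + sum(null_max >= r)) /
                (1 + n_perm), numeric(1))
  structure(list(
    table = tibble::tibble(variable = vars[!constant], weight = obs,
                           p_fwer = p, significant = abs(obs) > thr),
    excluded = vars[constant], threshold = thr, n_perm = n_perm,
    alpha = alpha, null_max = null_max), class = "backprojection")
}

#' @export
print.backprojection <- function(x, ...) {
  cat(sprintf("<backprojection: %d variables, %d significant at FWER %g>\n",
              nrow(x$table), sum(x$table$significant), x$alpha))
  invisible(x)
}

#' Align a mode's sign to an interpretive axis
#'
#' Canonical decompositions are sign-indeterminate: jointly negating one
#' mode's weights and both score vectors leaves every correlation
#' untouched. This fixes the convention by anchoring one variable (for
#' instance a substance-use measure held to the negative axis): if the
#' anchor's back-projected weight disagrees with the desired sign, all
#' weights and scores of that mode — and both back-projections — are
#' negated together. Applying the alignment twice restores the original
#' state.
#'
#' @param fit a `cca_fit`.
#' @param behavior_backproj,brain_backproj `backprojection` objects for
#'   the mode (the anchor is looked up in the behavioral one first).
#' @param anchor variable name to anchor.
#' @param desired_sign `"negative"` or `"positive"`.
#' @param mode mode index to align.
#' @return List with the (possibly negated) `fit`,
#'   `behavior_backproj`, `brain_backproj` and a `flipped` flag.
#' @export
align_signs <- function(fit, behavior_backproj, brain_backproj = NULL,
                        anchor, desired_sign = c("negative", "positive"),
                        mode = 1) {
  desired_sign <- match.arg(desired_sign)
  stopifnot(inherits(fit, "cca_fit"))
  tb <- behavior_backproj$table
  hit <- match(anchor, tb$variable)
  src <- behavior_backproj
  if (is.na(hit) && !is.null(brain_backproj)) {
    hit <- match(anchor, brain_backproj$table$variable)
    src <- brain_backproj
  }
  if (is.na(hit)) {
    warning("anchor '", anchor, "' not found; signs left unchanged")
    return(list(fit = fit, behavior_backproj = behavior_backproj,
                brain_backproj = brain_backproj, flipped = FALSE))
  }
  w <- src$table$weight[hit]
  want <- if (desired_sign == "negative") -1 else 1
  if (sign(w) == want || w == 0)
    return(list(fit = fit, behavior_backproj = behavior_backproj,
                brain_backproj = brain_backproj, flipped = FALSE))
  fit$xcoef[, mode] <- -fit$xcoef[, mode]
  fit$ycoef[, mode] <- -fit$ycoef[, mode]
  fit$xscores[, mode] <- -fit$xscores[, mode]
  fit$yscores[, mode] <- -fit$yscores[, mode]
  behavior_backproj$table$weight <- -behavior_backproj$table$weight
  if (!is.null(brain_backproj))
    brain_backproj$table$weight <- -brain_backproj$table$weight
  list(fit = fit, behavior_backproj = behavior_backproj,
       brain_backproj = brain_backproj, flipped = TRUE)
}

#' Four-correlation similarity between two CCA modes
#'
#' Compares an original and a control-analysis mode through the Pearson
#' correlations of (A) behavioral scores, (B) topographic scores, (C)
#' behavioral full-length weights and (D) topographic full-length
#' weights.
#'
#' @param a,b lists with elements `behavior_scores`, `topo_scores`,
#'   `behavior_weights`, `topo_weights`.
#' @return A `mode_similarity` tibble with one row per comparison.
#' @export
compare_modes <- function(a, b) {
  need <- c("behavior_scores", "topo_scores", "behavior_weights",
            "topo_weights")
  if (!all(need %in% names(a)) || !all(need %in% names(b)))
    abort_arg("modes need elements: ", paste(need, collapse = ", "))
  for (f in need)
    if (length(a[[f]]) != length(b[[f]]))
      abort_arg("mismatched spaces for ", f)
  out <- tibble::tibble(
    quantity = c("behavior_scores", "topography_scores",
                 "behavior_weights", "topography_weights"),
    r = c(cor(a$behavior_scores, b$behavior_scores),
          cor(a$topo_scores, b$topo_scores),
          cor(a$behavior_weights, b$behavior_weights),
          cor(a$topo_weights, b$topo_weights)))
  class(out) <- c("mode_similarity", class(out))
  out
}

#' Regress one topography set out of another
#'
#' Per participant, replaces the target ROI vector by its OLS residual
#' against an intercept plus the participant's regressor ROI vector —
#' the map-space control analysis (e.g. removing RVTCORR from GSCORR
#' before CCA).
#'
#' @param target,regressor participants x ROI matrices (same shape).
#' @return Residual matrix of the same shape.
#' @export
regress_out_map <- function(target, regressor) {
  target <- as.matrix(target)
  regressor <- as.matrix(regressor)
  if (!identical(dim(target), dim(regressor)))
    abort_arg("target and regressor must have identical shape")
  out <- target
  for (i in seq_len(nrow(target))) {
    r <- regressor[i, ]
    if (sd(r) == 0) abort_arg("constant regressor vector in row ", i)
    out[i, ] <- lm.fit(cbind(1, r), target[i, ])$residuals
  }
  out
}

#' Regress physiological series out of a frame series
#'
#' Time-domain control analysis: the target series is replaced by its
#' OLS residual against an intercept plus one or more regressor series.
#' Each regressor can be negated (`flip`) and shifted by an integer
#' frame lag (positive = backward, the regressor's sample at `t - lag`
#' paired with the target at `t`); the residual is returned on the
#' overlapping frames — `attr(, "frame_offset")` frames dropped at the
#' start and `attr(, "frame_tail")` at the end.
#'
#' @param target a [frame_series()] or numeric vector.
#' @param regressors list of frame series / numeric vectors (a single
#'   one may be passed directly).
#' @param lag_frames integer lag per regressor (recycled).
#' @param flip logical per regressor (recycled).
#' @return Residual [frame_series()].
#' @export
regress_out_series <- function(target, regressors, lag_frames = 0L,
                               flip = FALSE) {
  tv <- series_values(target)
  tr_s <- if (inherits(target, "frame_series")) target$tr_s else 1
  if (inherits(regressors, "frame_series") || is.numeric(regressors))
    regressors <- list(regressors)
  m <- length(regressors)
  lag_frames <- rep_len(as.integer(lag_frames), m)
  flip <- rep_len(flip, m)
  off <- max(c(lag_frames, 0L))
  tail <- max(c(-lag_frames, 0L))
  n <- length(tv)
  if (n - off - tail < 3 + m)
    abort_arg("overlap too short after lag alignment")
  cols <- lapply(seq_len(m), function(j) {
    rv <- series_values(regressors[[j]])
    if (length(rv) != n) abort_arg("regressor ", j, " length mismatch")
    if (flip[j]) rv <- -rv
    rv[(1 + off - lag_frames[j]):(n - tail - lag_frames[j])]
  })
  design <- cbind(1, do.call(cbind, cols))
  if (qr(design)$rank < ncol(design)) abort_arg("collinear regressors")
  resid <- lm.fit(design, tv[(1 + off):(n - tail)])$residuals
  out <- frame_series(as.numeric(resid), tr_s,
                      if (inherits(target, "frame_series"))
                        paste0(target$measure, "_resid") else "resid")
  attr(out, "frame_offset") <- off
  attr(out, "frame_tail") <- tail
  out
}
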