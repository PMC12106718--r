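# Behavioral-variable screening, deconfounding, nearest-SPD covariance
# completion, and component reduction for the two CCA blocks.

behavior_matrix <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"participant" %in% names(table))
    abort_arg("behavior table needs a participant column")
  m <- as.matrix(table[setdiff(names(table), "participant")])
  storage.mode(m) <- "double"
  rownames(m) <- table$participant
  m
}

#' Screen behavioral variables
#'
#' Applies the quantitative quality rules for behavioral batteries: a
#' measure is dropped when any value lies more than `sd_above_median`
#' standard deviations above its median (above only; symmetric screening
#' behind `symmetric`), when fewer than `min_valid_fraction` of its values
#' are non-missing, or when its modal value accounts for more than
#' `max_identical_fraction` of the non-missing entries. Explicitly listed
#' confounds and unwanted measures are removed with their own reason
#' codes. Every drop is recorded, so kept + dropped always equals the
#' input set.
#'
#' @param table tibble with a `participant` column and one column per
#'   measure.
#' @param sd_above_median outlier rule threshold (default 100 SDs).
#' @param min_valid_fraction minimum fraction of non-missing values.
#' @param max_identical_fraction maximum modal-value share.
#' @param confounds,drop character vectors of measures removed as
#'   confounds / as listed exclusions.
#' @param symmetric apply the SD rule in both directions.
#' @return A list of class `behavior_filter`: `table` (kept measures) and
#'   `report` (tibble measure / rule for every drop).
#' @export
filter_behavior_variables <- function(table, sd_above_median = 100,
                                      min_valid_fraction = 0.5,
                                      max_identical_fraction = 0.95,
                                      confounds = character(),
                                      drop = character(),
                                      symmetric = FALSE) {
  m <- behavior_matrix(table)
  measures <- colnames(m)
  reason <- setNames(rep(NA_character_, length(measures)), measures)
  reason[measures %in% confounds] <- "confound"
  reason[measures %in% drop & is.na(reason)] <- "listed"
  for (j in measures[is.na(reason)]) {
    x <- m[, j]
    valid <- !is.na(x)
    if (mean(valid) < min_valid_fraction) {
      reason[j] <- "too_few_valid"
      next
    }
    xv <- x[valid]
    s <- sd(xv)
    if (s > 0) {
      dev <- (xv - median(xv)) / s
      if (any(dev > sd_above_median) ||
          (symmetric && any(dev < -sd_above_median))) {
        reason[j] <- "extreme_outlier"
        next
      }
    }
    if (max(table(xv)) / length(xv) > max_identical_fraction)
      reason[j] <- "mostly_identical"
  }
  kept <- measures[is.na(reason)]
  if (!length(kept)) abort_arg("no behavioral measures survive screening")
  report <- tibble::tibble(measure = measures,
                           rule = unname(reason))[!is.na(reason), ]
  out <- tibble::as_tibble(table)[c("participant", kept)]
  structure(list(table = out, report = report,
                 n_input = length(measures), n_kept = length(kept)),
            class = "behavior_filter")
}

#' @export
print.behavior_filter <- function(x, ...) {
  cat(sprintf("<behavior_filter: %d of %d measures kept>\n",
              x$n_kept, x$n_input))
  if (nrow(x$report)) print(table(x$report$rule))
  invisible(x)
}

#' Remove confounds from a variable block
#'
#' Per variable: z-score using the non-missing entries, replace by the
#' OLS residual against an intercept plus the confound columns fitted on
#' that variable's non-missing rows, and rescale the residual back to
#' unit variance. Missing cells stay missing. The trailing rescaling
#' makes the operation exactly idempotent.
#'
#' @param x participants x variables matrix (missing allowed).
#' @param confounds participants x c numeric matrix, complete.
#' @return Residual matrix of the same shape, with the confound design in
#'   `attr(, "design")`.
#' @export
deconfound <- function(x, confounds) {
  x <- as.matrix(x)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(x))
    abort_arg("confounds must have one row per participant")
  if (anyNA(confounds)) abort_arg("confounds must be complete")
  design <- cbind(`(intercept)` = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort_arg("rank-deficient confound matrix; collinear column(s): ",
              paste(dropped, collapse = ", "))
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    obs <- !is.na(x[, j])
    v <- x[obs, j]
    s <- sd(v)
    v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    fit <- lm.fit(design[obs, , drop = FALSE], v)
    r <- fit$residuals
    s_r <- sd(r)
    # a residual SD at rounding-noise level means the variable was
    # fully explained by the confounds: keep the (numerically) zero
    # residual rather than amplifying float noise
    out[obs, j] <- if (is.finite(s_r) && s_r > 1e-8) r / s_r else r
  }
  attr(out, "design") <- design
  out
}

#' Nearest symmetric positive semidefinite matrix
#'
#' Symmetrizes, eigendecomposes, clips eigenvalues below
#' `eps_ratio * max(eigenvalue)` up to that floor, and reconstructs —
#' the fixed point of the symmetric-polar nearest-SPD construction for
#' symmetric input. Idempotent, and the identity on matrices that are
#' already positive semidefinite.
#'
#' @param m square numeric matrix.
#' @param eps_ratio eigenvalue floor relative to the largest eigenvalue.
#' @return Symmetric positive semidefinite matrix of the same dimension.
#' @export
nearest_spd <- function(m, eps_ratio = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort_arg("m must be square")
  sym <- (m + t(m)) / 2
  e <- eigen(sym, symmetric = TRUE)
  floor_val <- eps_ratio * max(e$values, 0)
  vals <- pmax(e$values, floor_val)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

new_component_scores <- function(scores, basis, explained, kind,
                                 center = NULL, scale = NULL,
                                 eigenvalues = NULL) {
  structure(list(scores = scores, basis = basis,
                 explained_variance_fraction = explained, kind = kind,
                 center = center, scale = scale,
                 eigenvalues = eigenvalues),
            class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("<component_scores (%s): %d participants x %d components, %.1f%% variance>\n",
              x$kind, nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance_fraction))
  invisible(x)
}

#' Behavioral component scores via covariance completion
#'
#' Handles missing behavioral cells by estimating the participants x
#' participants covariance of the normalized (and deconfounded) measures
#' from pairwise-complete observations — entry (i, j) is the
#' cross-product of participants i and j over their mutually observed
#' measures, divided by that count minus one — projecting it onto the
#' nearest positive semidefinite matrix ([nearest_spd()]), and taking
#' the top `k` eigenvectors scaled by the square root of their
#' eigenvalues as component scores. With complete data this reproduces
#' the span of ordinary PCA scores exactly. A regression basis
#' (pseudo-inverse of the zero-imputed deconfounded data onto the
#' scores) is retained so held-out participants can be projected during
#' cross-validation.
#'
#' @param x deconfounded participants x measures matrix (missing
#'   allowed; missing fraction must stay below `max_missing`).
#' @param k number of components (<= participants).
#' @param max_missing maximum tolerated missing fraction.
#' @return A `component_scores` object (`kind = "behavior"`).
#' @export
behavioral_components <- function(x, k = 100, max_missing = 0.2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) abort_arg("k cannot exceed the number of participants")
  miss <- mean(is.na(x))
  if (miss >= max_missing)
    abort_arg(sprintf("missing fraction %.1f%% exceeds %.0f%%",
                      100 * miss, 100 * max_missing))
  # columns are centered (z-scored upstream), so the participant x
  # participant covariance is the pairwise-complete Gram matrix
  x0 <- x
  x0[is.na(x0)] <- 0
  obs <- 1 - is.na(x)
  counts <- tcrossprod(obs)
  cc <- tcrossprod(x0) / pmax(counts - 1, 1)
  cc[counts < 2] <- 0
  cc <- nearest_spd(cc)
  e <- eigen(cc, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("comp_", seq_len(k))
  basis <- MASS_ginv(x0) %*% scores
  rownames(basis) <- colnames(x)
  new_component_scores(scores, basis,
                       sum(vals[seq_len(k)]) / sum(vals), "behavior",
                       eigenvalues = vals)
}

# Moore-Penrose pseudo-inverse via SVD (tolerance as in base qr)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Topographic component scores via SVD
#'
#' Column-standardizes the complete participants x ROI matrix, optionally
#' removes confounds, and reduces it by singular value decomposition:
#' scores are the left singular vectors scaled by the singular values,
#' and the right-singular basis is retained for projecting held-out
#' participants.
#'
#' @param x participants x ROI matrix, complete.
#' @param k number of components (<= min(participants, ROIs)).
#' @param confounds optional participants x c confound matrix.
#' @return A `component_scores` object (`kind = "topography"`).
#' @export
topography_components <- function(x, k = 100, confounds = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) abort_arg("topography matrix must be complete")
  if (k > min(dim(x))) abort_arg("k cannot exceed min(participants, ROIs)")
  z <- zscore_cols(x)
  xs <- z$x
  if (!is.null(confounds)) xs <- deconfound(xs, confounds)
  s <- svd(xs)
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("comp_", seq_len(k))
  basis <- s$v[, seq_len(k), drop = FALSE]
  rownames(basis) <- colnames(x)
  new_component_scores(scores, basis,
                       sum(s$d[seq_len(k)]^2) / sum(s$d^2), "topography",
                       center = z$center, scale = z$scale)
}

#' Project new participants onto fitted component scores
#'
#' For topographic components, new rows are standardized with the
#' training center/scale and multiplied by the right-singular basis. For
#' behavioral components, new (deconfounded) rows are zero-imputed and
#' passed through the stored regression basis.
#'
#' @param object a `component_scores` fit.
#' @param newdata matrix of new participant rows in the original variable
#'   space.
#' @param ... unused.
#' @return Matrix of component scores for the new rows.
#' @export
predict.component_scores <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(object$basis) != ncol(newdata))
    abort_arg("newdata has wrong number of variables")
  if (object$kind == "topography") {
    xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale,
                "/")
    return(xs %*% object$basis)
  }
  newdata[is.na(newdata)] <- 0
  newdata %*% object$basis
}
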