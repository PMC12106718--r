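# Plain-text serialization (TSV + JSON + YAML) and the end-to-end
# pipeline runner. No imaging formats: the analysis consumes ROI-level
# matrices, so TSV is the native container throughout.

check_tab_delimited <- function(path) {
  first <- readLines(path, n = 5)
  first <- first[!startsWith(first, "#")]
  if (length(first) && !any(grepl("\t", first)) &&
      any(grepl(",", first)))
    abort_arg(path, ": comma-delimited input where TSV expected")
}

#' Read a BOLD run matrix
#'
#' TSV with ROI rows and frame columns; ROI identifiers in the first
#' column. The repetition time is read from a `# tr_s=` header line or
#' supplied explicitly.
#'
#' @param path TSV file path.
#' @param tr_s repetition time (overrides any header).
#' @return A [run_series()].
#' @export
read_bold_run <- function(path, tr_s = NULL) {
  check_tab_delimited(path)
  header <- grep("^# tr_s=", readLines(path, n = 3), value = TRUE)
  if (is.null(tr_s)) {
    if (!length(header)) abort_arg(path, ": no TR header and no tr_s given")
    tr_s <- as.numeric(sub("^# tr_s=", "", header[1]))
  }
  d <- utils::read.delim(path, comment.char = "#", header = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (anyNA(m)) abort_arg(path, ": NaN/NA in BOLD matrix")
  rownames(m) <- d[[1]]
  run_series(m, tr_s, d[[1]])
}

#' Write a BOLD run matrix
#' @param run a [run_series()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s=%.17g", run$tr_s), con)
  utils::write.table(cbind(roi = run$roi_ids,
                           format(run$bold, digits = 17, trim = TRUE)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a physiological trace
#'
#' One sample per line, with the sampling rate in a `# fs=` header.
#'
#' @param path file path.
#' @param kind `"respiratory"` or `"cardiac"`.
#' @return A raw [physio_trace()].
#' @export
read_physio_trace <- function(path, kind = c("respiratory", "cardiac")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- grep("^# fs=", lines, value = TRUE)
  if (!length(hdr)) abort_arg(path, ": missing '# fs=' header")
  fs <- as.numeric(sub("^# fs=", "", hdr[1]))
  x <- as.numeric(lines[!startsWith(lines, "#")])
  if (anyNA(x)) abort_arg(path, ": non-numeric samples")
  physio_trace(x, fs, kind, "raw")
}

#' Write a physiological trace
#' @param trace a [physio_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_physio_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", trace$fs), con)
  writeLines(format(trace$samples, digits = 17, trim = TRUE), con)
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path) {
  check_tab_delimited(path)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Write a synthetic cohort to a directory
#'
#' Runs as TSV matrices (ROI rows x frame columns), physiological traces
#' as one-column text with a `# fs=` header, behavior / family / atlas
#' tables as TSV, and the ground truth as JSON.
#'
#' @param cohort a `physiocca_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$runs)) {
    p <- cohort$participants[i]
    for (r in seq_along(cohort$runs[[i]])) {
      write_bold_run(cohort$runs[[i]][[r]],
                     file.path(dir, sprintf("%s_run%d_bold.tsv", p, r)))
      if (!is.null(cohort$resp_traces)) {
        write_physio_trace(cohort$resp_traces[[i]][[r]],
                           file.path(dir, sprintf("%s_run%d_resp.txt",
                                                  p, r)))
        write_physio_trace(cohort$cardiac_traces[[i]][[r]],
                           file.path(dir, sprintf("%s_run%d_card.txt",
                                                  p, r)))
      }
    }
  }
  write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  write_tsv(cohort$family, file.path(dir, "family.tsv"))
  write_tsv(cohort$atlas, file.path(dir, "atlas.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort directory with validation
#'
#' Reads what [write_cohort()] produced, checking roster consistency
#' (behavior and family tables must name the same participants as the
#' run files), delimiter sanity and BOLD finiteness.
#'
#' @param dir cohort directory.
#' @param tr_s repetition time override.
#' @return A list with `runs`, `resp_traces`, `cardiac_traces`,
#'   `behavior`, `family`, `atlas`, `participants`.
#' @export
load_dataset <- function(dir, tr_s = NULL) {
  behavior <- read_tsv_checked(file.path(dir, "behavior.tsv"))
  family <- read_tsv_checked(file.path(dir, "family.tsv"))
  atlas <- read_tsv_checked(file.path(dir, "atlas.tsv"))
  run_files <- sort(list.files(dir, "_bold\\.tsv$", full.names = TRUE))
  if (!length(run_files)) abort_arg("no *_bold.tsv runs in ", dir)
  parts <- unique(sub("_run\\d+_bold\\.tsv$", "", basename(run_files)))
  unknown <- setdiff(behavior$participant, parts)
  if (length(unknown))
    abort_arg("behavior table names unknown participant(s): ",
              paste(unknown, collapse = ", "))
  unknown <- setdiff(family$participant, parts)
  if (length(unknown))
    abort_arg("family table names unknown participant(s): ",
              paste(unknown, collapse = ", "))
  runs <- lapply(parts, function(p) {
    files <- sort(grep(paste0("^", p, "_run\\d+_bold\\.tsv$"),
                       basename(run_files), value = TRUE))
    lapply(file.path(dir, files), read_bold_run, tr_s = tr_s)
  })
  names(runs) <- parts
  read_traces <- function(tag, kind) {
    files <- list.files(dir, paste0("_", tag, "\\.txt$"))
    if (!length(files)) return(NULL)
    out <- lapply(parts, function(p) {
      fs <- sort(grep(paste0("^", p, "_run\\d+_", tag, "\\.txt$"),
                      files, value = TRUE))
      lapply(file.path(dir, fs), read_physio_trace, kind = kind)
    })
    names(out) <- parts
    out
  }
  list(runs = runs,
       resp_traces = read_traces("resp", "respiratory"),
       cardiac_traces = read_traces("card", "cardiac"),
       behavior = behavior, family = family, atlas = atlas,
       participants = parts)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end run with their defaults: cohort size,
#' acquisition grid (TR 0.72 s, 400 Hz physiology), truncation (10
#' frames), lag window (72 s), component count, permutation counts and
#' alphas, CV folds, and one seed from which each stage derives its own.
#' Round-trips through YAML unchanged.
#'
#' @param ... overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_participants = 60, n_roi = 60, n_frames = 420, tr_s = 0.72,
    n_runs = 1, physio_fs = 400, keep_traces = FALSE,
    missing_rate = 0.0093, truncate = 10, max_lag_s = 72,
    k_components = 15, n_perm_modes = 1000, n_perm_backproject = 2000,
    alpha_backproject = 0.001, cv_folds = 10, n_perm_cv = 500,
    alpha_fold = 0.005, icc_variant = "paper", seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort_arg("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Chains all stages — simulate, physiological preprocessing check,
#' topographies, ICC, behavioral preparation, permutation CCA, and
#' cross-validated CCA — writing each stage's outputs as TSV/JSON under
#' `out_dir` together with a manifest recording stage order, seeds and
#' per-file checksums. Re-running with the same configuration reproduces
#' every stochastic output bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return The manifest list, invisibly readable from
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  outputs <- character()
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }
  emit <- function(name) outputs <<- c(outputs, name)

  cohort <- stage("simulate", generate_cohort(
    config$n_participants, config$n_roi, config$n_frames, config$tr_s,
    config$n_runs, cohort_truth_config(),
    missing_rate = config$missing_rate, physio_fs = config$physio_fs,
    keep_traces = config$keep_traces, seed = config$seed))
  write_tsv(cohort$behavior, file.path(out_dir, "behavior.tsv"))
  write_tsv(cohort$family, file.path(out_dir, "family.tsv"))
  write_tsv(cohort$atlas, file.path(out_dir, "atlas.tsv"))
  emit(c("behavior.tsv", "family.tsv", "atlas.tsv"))

  physio <- stage("physio", {
    # frame-grid physiology for every run (from the generator's truth
    # grid, or the full trace pipeline when traces were materialized)
    if (!is.null(cohort$resp_traces)) {
      lapply(seq_along(cohort$runs), function(i)
        lapply(seq_along(cohort$runs[[i]]), function(r) {
          tr <- clean_respiratory_trace(cohort$resp_traces[[i]][[r]])
          rvt <- derive_respiration_measure(tr, "rvt")
          resample_to_frames(rvt, tr$fs, config$n_frames, config$tr_s)
        }))
    } else cohort$frame_physio
  })

  topo <- stage("topo", {
    gscorr <- cohort_topographies(cohort, "gscorr",
                                  n_edge = config$truncate)
    rvtcorr <- cohort_topographies(cohort, "rvtcorr",
                                   n_edge = config$truncate,
                                   max_lag_s = config$max_lag_s)
    write_tsv(cbind(tibble::tibble(participant = rownames(gscorr)),
                    tibble::as_tibble(gscorr)),
              file.path(out_dir, "gscorr.tsv"))
    write_tsv(cbind(tibble::tibble(participant = rownames(rvtcorr)),
                    tibble::as_tibble(rvtcorr)),
              file.path(out_dir, "rvtcorr.tsv"))
    emit(c("gscorr.tsv", "rvtcorr.tsv"))
    list(gscorr = gscorr, rvtcorr = rvtcorr)
  })

  icc <- stage("icc", {
    m <- icc_two_way(topo$gscorr, topo$rvtcorr,
                     variant = config$icc_variant)
    ns <- network_icc_summary(m, cohort$atlas)
    write_tsv(m$table, file.path(out_dir, "icc.tsv"))
    jsonlite::write_json(list(kruskal_h = ns$kruskal_h,
                              p_value = ns$p_value),
                         file.path(out_dir, "icc_networks.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(c("icc.tsv", "icc_networks.json"))
    m
  })

  prep <- stage("prep", {
    filt <- filter_behavior_variables(cohort$behavior)
    bm <- behavior_matrix(filt$table)
    zb <- zscore_cols(bm)
    k <- min(config$k_components, ncol(bm), nrow(bm))
    beh_cs <- behavioral_components(zb$x, k = k)
    topo_cs <- topography_components(topo$rvtcorr, k = k)
    write_tsv(filt$report, file.path(out_dir, "behavior_exclusions.tsv"))
    emit("behavior_exclusions.tsv")
    list(beh = beh_cs, topo = topo_cs, filter = filt)
  })

  cca <- stage("cca", {
    pt <- permutation_test_modes(prep$topo, prep$beh, cohort$family,
                                 n_perm = config$n_perm_modes,
                                 seed = child_seed(config$seed, "modes"))
    bp <- backproject_weights(pt$fit$yscores[, 1],
                              behavior_matrix(prep$filter$table),
                              cohort$family,
                              n_perm = config$n_perm_backproject,
                              alpha = config$alpha_backproject,
                              seed = child_seed(config$seed, "bp"))
    write_tsv(pt$table, file.path(out_dir, "cca_modes.tsv"))
    write_tsv(bp$table, file.path(out_dir, "cca_behavior_weights.tsv"))
    emit(c("cca_modes.tsv", "cca_behavior_weights.tsv"))
    list(perm = pt, backproj = bp)
  })

  cv <- stage("cv", {
    plan <- family_aware_folds(cohort$family, k = config$cv_folds,
                               seed = child_seed(config$seed, "folds"))
    rep <- cross_validate_cca(topo$rvtcorr,
                              behavior_matrix(prep$filter$table),
                              plan, k_components = prep$beh |>
                                (\(b) ncol(b$scores))())
    rep <- cv_permutation_significance(rep, n_perm = config$n_perm_cv,
                                       seed = child_seed(config$seed,
                                                         "cvperm"),
                                       alpha_fold = config$alpha_fold)
    write_tsv(rep$table, file.path(out_dir, "cv_folds.tsv"))
    jsonlite::write_json(list(mean_oos_r = rep$mean_oos_r,
                              p_mean = rep$perm$p_mean,
                              any_fold_significant =
                                rep$perm$any_fold_significant,
                              weight_stability_brain =
                                rep$weight_stability_brain,
                              weight_stability_behavior =
                                rep$weight_stability_behavior),
                         file.path(out_dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(c("cv_folds.tsv", "cv_summary.json"))
    rep
  })

  files <- unlist(outputs)
  manifest <- list(stages = stages,
                   seed = config$seed,
                   config = unclass(config),
                   checksums = as.list(tools::md5sum(
                     file.path(out_dir, files))) |>
                     setNames(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read or write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
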