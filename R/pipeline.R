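# Pipeline orchestration: synthetic cohort (or centroid CSV inputs) ->
# 490-feature table -> selection -> classifier sweep -> baselines ->
# feature statistics, with every stage writing documented CSV/JSON
# artefacts and a manifest recording seeds, parameters and content hashes.

#' Run the full prognosis-assessment pipeline
#'
#' @param config list with entries:
#'   \describe{
#'     \item{outdir}{artefact directory (created).}
#'     \item{seed}{master seed.}
#'     \item{cohort}{list passed to [gen_cohort()] (synthetic input), or}
#'     \item{features_csv,labels_csv}{pre-computed inputs; `labels_csv`
#'       needs columns `label`, `histology`, `ki67_li`, `density_per_mm2`.}
#'     \item{selection}{list: `cv_reps`, `lambda_grid` (optional).}
#'     \item{classify}{list: `models`, `n_range`, `reps`.}
#'   }
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir), !is.null(config$seed))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  artefacts <- character(0)

  # stage 1: features
  if (!is.null(config$features_csv)) {
    feats <- read.csv(config$features_csv, check.names = FALSE)
    meta <- read.csv(config$labels_csv)
    need <- c("label", "histology", "ki67_li", "density_per_mm2")
    miss <- setdiff(need, names(meta))
    if (length(miss))
      stop("schema error in labels table: missing column(s) ",
           paste(miss, collapse = ", "))
    labels <- meta$label; histology <- meta$histology
    ki67_li <- meta$ki67_li; density <- meta$density_per_mm2
  } else {
    co <- do.call(gen_cohort, c(config$cohort, list(seed = seed)))
    feats <- co$features
    labels <- co$labels; histology <- co$histology
    ki67_li <- co$ki67_li; density <- co$density_per_mm2
  }
  fpath <- file.path(outdir, "features.csv")
  write.csv(cbind(data.frame(label = labels, histology = histology,
                             ki67_li = ki67_li, density_per_mm2 = density),
                  feats), fpath, row.names = FALSE)
  artefacts <- c(artefacts, fpath)

  # stage 2: selection
  selcfg <- if (is.null(config$selection)) list() else config$selection
  filt <- drop_perfectly_correlated(drop_constant(feats))
  sel <- nca_select(filt, labels,
                    lambda_grid = selcfg$lambda_grid,
                    cv_reps = if (is.null(selcfg$cv_reps)) 100
                    else selcfg$cv_reps,
                    seed = seed)
  wpath <- file.path(outdir, "nca_weights.csv")
  write.csv(data.frame(feature = names(sel$weights),
                       weight = as.numeric(sel$weights)), wpath,
            row.names = FALSE)
  rpath <- file.path(outdir, "ranking.json")
  jsonlite::write_json(list(lambda = sel$lambda, ranking = sel$ranking,
                            retained = sel$retained), rpath,
                       auto_unbox = TRUE, digits = NA)
  artefacts <- c(artefacts, wpath, rpath)

  # stage 3: classifier sweep over n top features
  clcfg <- if (is.null(config$classify)) list() else config$classify
  models <- if (is.null(clcfg$models)) c("knn", "svm") else clcfg$models
  n_max <- max(3, length(sel$retained))
  n_range <- if (is.null(clcfg$n_range)) 3:min(23, n_max) else clcfg$n_range
  reps <- if (is.null(clcfg$reps)) 100 else clcfg$reps
  folds <- if (is.null(clcfg$folds)) 5 else clcfg$folds
  Xr <- as.matrix(filt[, sel$ranking, drop = FALSE])
  sweep_rows <- list()
  reports <- list()
  for (mdl in models) {
    for (nf in n_range) {
      if (nf > ncol(Xr)) next
      rep_ <- repeated_cv(Xr, labels, model = mdl, n_features = nf,
                          reps = reps, folds = folds, seed = seed,
                          histology = histology)
      reports[[paste0(mdl, "_", nf)]] <- rep_
      sweep_rows[[length(sweep_rows) + 1L]] <-
        data.frame(model = mdl, n_features = nf,
                   t(rep_$metrics), accuracy_se = rep_$se[["accuracy"]])
    }
  }
  sweep_df <- do.call(rbind, sweep_rows)
  spath <- file.path(outdir, "cv_sweep.csv")
  write.csv(sweep_df, spath, row.names = FALSE)
  artefacts <- c(artefacts, spath)

  # stage 4: single-metric baselines
  bl <- list(ki67_li = threshold_baseline(ki67_li, labels),
             density_per_mm2 = threshold_baseline(density, labels))
  bpath <- file.path(outdir, "baselines.json")
  jsonlite::write_json(lapply(bl, function(b)
    list(optimal_threshold = b$optimal_threshold, accuracy = b$accuracy,
         report = as.list(b$report))), bpath, auto_unbox = TRUE, digits = NA)
  artefacts <- c(artefacts, bpath)

  # stage 5: feature statistics
  fs <- feature_set_report(filt, sel$ranking, ki67_li, density, histology)
  stpath <- file.path(outdir, "feature_stats.csv")
  write.csv(fs$per_feature, stpath, row.names = FALSE)
  vpath <- file.path(outdir, "venn.json")
  jsonlite::write_json(as.list(fs$venn_counts), vpath, auto_unbox = TRUE,
                       digits = NA)
  artefacts <- c(artefacts, stpath, vpath)

  # manifest
  hashes <- tools::md5sum(artefacts)
  manifest <- list(package_version = as.character(utils::packageVersion("ki67spatial")),
                   seed = seed,
                   config_hash = digest::digest(config),
                   artefacts = as.list(hashes),
                   manifest_hash = digest::digest(unname(hashes)))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)

  invisible(list(selection = sel, sweep = sweep_df, baselines = bl,
                 feature_stats = fs, manifest = manifest))
}
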