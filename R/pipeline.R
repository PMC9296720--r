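#' Configuration for the end-to-end study replica
#'
#' Bundles the phantom, ROI, texture, selection and classifier parameters of
#' one run. Fully serializable; [run_full_pipeline()] writes the resolved
#' configuration next to its outputs so a run directory suffices to rerun
#' identically.
#'
#' @param phantom a [phantom_config()].
#' @param n_per_class examinations per density class (default 50).
#' @param margin_mm ROI skin margin (default 5).
#' @param n_levels grey levels for quantisation (default 64).
#' @param distance GLCM offset distance (default 1).
#' @param directions in-plane directions for GLCM/GLRLM.
#' @param feature_set classifier inputs: `"anova"` (the Step-1 survivors,
#'   default), `"all19"`, or `"retained"`.
#' @param train_frac training fraction (default 0.7, must be in (0, 1)).
#' @param ridge classifier L2 penalty (default 1e-4).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            n_per_class = 50L,
                            margin_mm = 5,
                            n_levels = 64L,
                            distance = 1L,
                            directions = c("0", "45", "90", "135"),
                            feature_set = c("anova", "all19", "retained"),
                            train_frac = 0.7,
                            ridge = 1e-4,
                            seed = 1L) {
  feature_set <- match.arg(feature_set)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (n_per_class < 2) stop("n_per_class must be >= 2 for a stratified split")
  structure(
    list(phantom = phantom, n_per_class = as.integer(n_per_class),
         margin_mm = margin_mm, n_levels = as.integer(n_levels),
         distance = as.integer(distance), directions = directions,
         feature_set = feature_set, train_frac = train_frac, ridge = ridge,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Run the full study replica
#'
#' Generates the balanced phantom cohort (streaming), extracts the 19-feature
#' table, runs the feature-selection cascade, fits and evaluates the
#' multinomial density classifier, and (when `out_dir` is given) writes the
#' feature table, selection report, model, confusion matrices, metrics and the
#' resolved configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list: `features` (table), `selection` (report), `classifier`
#'   (evaluation), `config`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tb <- build_feature_table(config$phantom, config$n_per_class,
                            seed = config$seed, margin_mm = config$margin_mm,
                            n_levels = config$n_levels,
                            distance = config$distance,
                            directions = config$directions)
  sel <- run_feature_selection(tb)
  feats <- switch(config$feature_set,
                  all19 = texture_feature_names(),
                  anova = sel$candidates,
                  retained = sel$retained)
  if (length(feats) == 0) stop("classifier stage: empty feature set")
  cls <- evaluate_classifier(tb, feats, train_frac = config$train_frac,
                             seed = config$seed, ridge = config$ridge)
  res <- list(features = tb, selection = sel, classifier = cls,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(tb, file.path(out_dir, "feature_table.csv"))
    write_selection_report(sel, file.path(out_dir, "selection"))
    write_density_model(cls$model, file.path(out_dir, "model.json"))
    utils::write.csv(as.matrix(cls$test_confusion),
                     file.path(out_dir, "test_confusion.csv"))
    jsonlite::write_json(
      list(train = cls$train_metrics, test = cls$test_metrics,
           features_used = feats),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    cfg <- config
    cfg$phantom <- unclass(cfg$phantom)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
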