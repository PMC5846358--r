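#' Run the full before/after analysis pipeline
#'
#' Convenience wrapper chaining the individual modules over a two-phase
#' study: 5-s segmentation and feature extraction for every track, seeded
#' subsampling of training segments pooled across subjects, min-max
#' normalization, SOM training, Ward clustering into six named patterns,
#' classification of *all* segments, windowed fractal dimensions, and the
#' paired before/after statistical report.
#'
#' @param study List with elements `before` and `after`, each a list of
#'   `"daph_track"` objects (e.g. from [default_study()]).
#' @param train_per_phase Number of 5-s segments per phase used to train the
#'   SOM (default 1000).
#' @param stop_speed_threshold Stop threshold in mm/s (default 1).
#' @param som_rows,som_cols,epochs SOM settings (default 8 x 8, 10 epochs).
#' @param window_s_fractal Fractal window in seconds (default 600).
#' @param M Raster size for the fractal analysis (default 256).
#' @param seed Integer seed for subsampling and SOM training.
#' @param alpha Significance level for the report (default 0.01).
#' @return List with `report` (a `"phase_report"`), `model`, `clusters`,
#'   `features` (per-phase feature matrices), `labels` (per-phase label data
#'   frames) and `fractal` (per-phase windowed-D data frames).
#' @export
analyze_study <- function(study, train_per_phase = 1000,
                          stop_speed_threshold = 1.0,
                          som_rows = 8, som_cols = 8, epochs = 10,
                          window_s_fractal = 600, M = 256,
                          seed = 1, alpha = 0.01) {
  stopifnot(all(c("before", "after") %in% names(study)))
  feats <- lapply(study[c("before", "after")], function(tracks) {
    segs <- unlist(lapply(tracks, segment_track, window_s = 5), recursive = FALSE)
    build_feature_matrix(segs, stop_speed_threshold = stop_speed_threshold)
  })

  set.seed(seed)
  take <- function(fm, n) fm[sample.int(nrow(fm), min(n, nrow(fm))), , drop = FALSE]
  train_fm <- rbind(take(feats$before, train_per_phase),
                    take(feats$after, train_per_phase))
  norm <- normalize_features(train_fm)
  model <- train_som(norm$data, som_rows = som_rows, som_cols = som_cols,
                     epochs = epochs, seed = seed, normalization = norm$stats)
  clusters <- name_patterns(model, ward_cluster(model, k = 6))

  labels <- lapply(feats, function(fm) {
    data.frame(subject_id = fm$subject_id, phase = fm$phase,
               segment = fm$segment,
               pattern = classify_segments(model, clusters, fm))
  })

  fractal <- lapply(study[c("before", "after")], function(tracks) {
    do.call(rbind, lapply(tracks, fractal_report,
                          window_s = window_s_fractal, M = M))
  })

  report <- compare_phases(feats$before, feats$after,
                           fractal$before, fractal$after,
                           labels$before, labels$after, alpha = alpha)
  list(report = report, model = model, clusters = clusters,
       features = feats, labels = labels, fractal = fractal)
}
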