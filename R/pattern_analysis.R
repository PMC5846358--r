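#' Pattern composition of a set of classified segments
#'
#' Counts and percentages of the six movement patterns P1..P6 among a set of
#' labels, zero-filled for absent patterns.
#'
#' @param labels Character vector of pattern labels (subset of P1..P6).
#' @return Object of class `"pattern_composition"`: data frame with columns
#'   `pattern`, `count`, `percentage` (summing to 100).
#' @examples
#' composition(c("P1", "P1", "P1", "P6"))
#' @export
composition <- function(labels) {
  if (length(labels) == 0L) stop("no labels supplied")
  lv <- names(pattern_archetypes())
  bad <- setdiff(unique(labels), lv)
  if (length(bad)) stop("unknown pattern label: ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = lv))
  structure(data.frame(pattern = lv,
                       count = as.integer(counts),
                       percentage = 100 * as.numeric(counts) / length(labels)),
            class = c("pattern_composition", "data.frame"))
}

#' One-tailed paired-sample t-test
#'
#' Classical paired t statistic on per-subject differences d = before -
#' after: t = mean(d) / (sd(d)/sqrt(n)) with sample standard deviation
#' (n - 1 denominator) and df = n - 1. The alternative direction must be
#' declared a priori: `"greater"` tests mean(d) > 0 (the endpoint decreases
#' after treatment), `"less"` tests mean(d) < 0 (it increases).
#'
#' @param before,after Paired per-subject values, equal length >= 2.
#' @param direction `"greater"` or `"less"` (alternative for
#'   mean(before - after)).
#' @return Object of class `"paired_t_result"`: list with `t`, `df`, `p`,
#'   `direction`, `n`, `mean_diff`.
#' @examples
#' paired_t_test(c(5, 6, 7, 8), c(4, 4, 4, 4), "greater")  # t = 3.873, df 3
#' @export
paired_t_test <- function(before, after, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(before) != length(after)) stop("before/after lengths differ")
  n <- length(before)
  if (n < 2L) stop("need at least 2 pairs")
  d <- before - after
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences; t undefined")
  tstat <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  p <- if (direction == "greater") stats::pt(tstat, df, lower.tail = FALSE)
       else stats::pt(tstat, df)
  structure(list(t = tstat, df = df, p = p, direction = direction,
                 n = n, mean_diff = mean(d)),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t = %.3f, df = %d, one-tailed (%s) p = %.4g\n",
              x$t, x$df, x$direction, x$p))
  invisible(x)
}

# default a-priori alternative per endpoint: activity falls, turning and
# stopping rise after an adverse treatment
default_directions <- function() {
  list(
    parameters = c(speed = "greater", acceleration = "greater",
                   locomotory_rate = "greater", stop_number = "less",
                   stop_time = "less", turning_rate = "less", meander = "less"),
    fractal = "greater",
    patterns = c(P1 = "greater", P2 = "greater", P3 = "greater",
                 P4 = "less", P5 = "less", P6 = "less")
  )
}

paired_endpoint_table <- function(wide, subjects, direction) {
  b <- wide[match(subjects, wide$subject_id), "before"]
  a <- wide[match(subjects, wide$subject_id), "after"]
  tt <- paired_t_test(b, a, direction)
  data.frame(mean_before = mean(b), sd_before = stats::sd(b),
             mean_after = mean(a), sd_after = stats::sd(a),
             t = tt$t, df = tt$df, p = tt$p, direction = direction)
}

per_subject_mean <- function(df, value_col) {
  agg <- stats::aggregate(df[[value_col]],
                          by = list(subject_id = df$subject_id, phase = df$phase),
                          FUN = mean)
  stats::reshape(agg, idvar = "subject_id", timevar = "phase", direction = "wide")
}

#' Before/after comparison report
#'
#' Builds the full treatment comparison from per-segment features, windowed
#' fractal dimensions and pattern labels of both phases: per-subject means
#' of each movement parameter, per-subject mean fractal dimension and
#' per-subject pattern percentages, each compared across phases with a
#' one-tailed paired t-test. Pattern proportions are computed per subject
#' and then paired across subjects, so with 10 subjects every test has
#' df = 9.
#'
#' @param features_before,features_after Feature matrices (data frames from
#'   [build_feature_matrix()]) with `subject_id` columns.
#' @param fd_before,fd_after Data frames with columns `subject_id` and `D`
#'   (e.g. row-bound [fractal_report()] outputs).
#' @param labels_before,labels_after Data frames with columns `subject_id`
#'   and `pattern`.
#' @param directions Optional list overriding [the default] a-priori test
#'   directions; elements `parameters`, `fractal`, `patterns`.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.01).
#' @param bonferroni If `TRUE`, `alpha` is divided by the number of pattern
#'   tests before flagging (off by default, matching single-endpoint
#'   reporting).
#' @return Object of class `"phase_report"`: list of data frames
#'   `parameters`, `fractal`, `patterns` (each with mean/sd per phase, t,
#'   df, p, direction, significant) plus `pattern_percentages` (per subject
#'   and phase).
#' @export
compare_phases <- function(features_before, features_after,
                           fd_before, fd_after,
                           labels_before, labels_after,
                           directions = NULL, alpha = 0.01,
                           bonferroni = FALSE) {
  dirs <- default_directions()
  if (!is.null(directions)) dirs[names(directions)] <- directions
  subjects <- sort(unique(features_before$subject_id))
  for (df in list(features_after, fd_before, fd_after, labels_before, labels_after)) {
    if (!setequal(unique(df$subject_id), subjects))
      stop("subject sets differ between the supplied phases")
  }

  feats <- rbind(cbind(features_before, .phase = "before"),
                 cbind(features_after, .phase = "after"))
  feats$phase <- feats$.phase

  par_rows <- lapply(feature_names(), function(p) {
    wide <- per_subject_mean(feats, p)
    names(wide) <- sub(paste0("^x\\."), "", names(wide))
    cbind(endpoint = p,
          paired_endpoint_table(wide, subjects, dirs$parameters[[p]]))
  })
  parameters <- do.call(rbind, par_rows)

  fd <- rbind(cbind(fd_before[, c("subject_id", "D")], phase = "before"),
              cbind(fd_after[, c("subject_id", "D")], phase = "after"))
  wide_fd <- per_subject_mean(fd, "D")
  names(wide_fd) <- sub("^x\\.", "", names(wide_fd))
  fractal <- cbind(endpoint = "fractal_dimension",
                   paired_endpoint_table(wide_fd, subjects, dirs$fractal))

  pct <- subject_pattern_percentages(rbind(
    cbind(labels_before[, c("subject_id", "pattern")], phase = "before"),
    cbind(labels_after[, c("subject_id", "pattern")], phase = "after")))
  pat_rows <- lapply(names(pattern_archetypes()), function(pn) {
    sub <- pct[pct$pattern == pn, ]
    wide <- stats::reshape(sub[, c("subject_id", "phase", "percentage")],
                           idvar = "subject_id", timevar = "phase",
                           direction = "wide")
    names(wide) <- sub("^percentage\\.", "", names(wide))
    cbind(endpoint = pn,
          paired_endpoint_table(wide, subjects, dirs$patterns[[pn]]))
  })
  patterns <- do.call(rbind, pat_rows)

  a_pat <- if (bonferroni) alpha / nrow(patterns) else alpha
  parameters$significant <- parameters$p < alpha
  fractal$significant <- fractal$p < alpha
  patterns$significant <- patterns$p < a_pat
  rownames(parameters) <- rownames(patterns) <- NULL

  structure(list(parameters = parameters, fractal = fractal,
                 patterns = patterns, pattern_percentages = pct,
                 alpha = alpha, subjects = subjects),
            class = "phase_report")
}

#' Per-subject pattern percentages
#'
#' @param labels Data frame with columns `subject_id`, `phase`, `pattern`.
#' @return Data frame `subject_id`, `phase`, `pattern`, `count`,
#'   `percentage`, zero-filled so every subject/phase has all six patterns.
#' @export
subject_pattern_percentages <- function(labels) {
  out <- do.call(rbind, lapply(split(labels, list(labels$subject_id, labels$phase),
                                     drop = TRUE), function(g) {
    comp <- composition(g$pattern)
    data.frame(subject_id = g$subject_id[1L], phase = g$phase[1L],
               pattern = comp$pattern, count = comp$count,
               percentage = comp$percentage)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.phase_report <- function(x, ...) {
  fmt <- function(df) {
    df$p <- signif(df$p, 3)
    for (cc in c("mean_before", "sd_before", "mean_after", "sd_after", "t"))
      df[[cc]] <- round(df[[cc]], 3)
    df
  }
  cat("Movement parameters (per-subject means, paired one-tailed t):\n")
  print(fmt(x$parameters), row.names = FALSE)
  cat("\nFractal dimension (10-min windows, per-subject means):\n")
  print(fmt(x$fractal), row.names = FALSE)
  cat("\nPattern percentages (per subject, paired across phases):\n")
  print(fmt(x$patterns), row.names = FALSE)
  invisible(x)
}

#' Write a phase report to JSON
#'
#' Machine-readable export of [compare_phases()] output.
#'
#' @param report A `"phase_report"`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(parameters = report$parameters,
                            fractal = report$fractal,
                            patterns = report$patterns,
                            alpha = report$alpha),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
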