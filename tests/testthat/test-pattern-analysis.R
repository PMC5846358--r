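test_that("composition tallies match an independent count", {
  c1 <- composition(rep("P1", 10))
  expect_equal(c1$percentage[c1$pattern == "P1"], 100)
  expect_equal(sum(c1$percentage), 100)

  c2 <- composition(c(rep("P1", 3), "P6"))
  expect_equal(c2$percentage[c2$pattern == "P1"], 75)
  expect_equal(c2$percentage[c2$pattern == "P6"], 25)
  expect_equal(c2$count[c2$pattern == "P3"], 0L)

  set.seed(8)
  labs <- sample(names(pattern_archetypes()), 500, replace = TRUE,
                 prob = c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05))
  cc <- composition(labs)
  tab <- table(factor(labs, levels = names(pattern_archetypes())))
  expect_equal(cc$count, unname(as.integer(tab)))
  expect_equal(sum(cc$percentage), 100, tolerance = 1e-9)

  expect_error(composition(character(0)), "no labels")
  expect_error(composition(c("P1", "P9")), "unknown")
})

test_that("paired t statistic matches its definition and the reference test", {
  # hand-worked 4-pair example: differences 1,2,3,4
  r <- paired_t_test(c(5, 6, 7, 8), c(4, 4, 4, 4), "greater")
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3L)

  # n = 10 pairs -> df = 9
  set.seed(10)
  r10 <- paired_t_test(rnorm(10, 1), rnorm(10), "greater")
  expect_equal(r10$df, 9L)

  # agreement with the independent reference implementation
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    b <- rnorm(n, sd = runif(1, 0.5, 3)); a <- rnorm(n, mean = runif(1, -1, 1))
    dir <- sample(c("greater", "less"), 1)
    ours <- paired_t_test(b, a, dir)
    ref <- t.test(b, a, paired = TRUE, alternative = dir)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter))
  }

  # degenerate contracts
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3), "greater"), "zero variance")
  expect_error(paired_t_test(1:4, 1:3, "greater"), "lengths differ")
  expect_error(paired_t_test(5, 4, "greater"), "at least 2")
})

test_that("type-I error of the one-tailed test stays near nominal under the null", {
  set.seed(40)
  rej <- 0L; n_rep <- 400L
  for (rep in seq_len(n_rep)) {
    b <- rnorm(10); a <- rnorm(10)
    rej <- rej + (paired_t_test(b, a, "greater")$p < 0.01)
  }
  expect_lte(rej / n_rep, 0.03)
})

test_that("phase comparison report is structurally sound on null-like data", {
  set.seed(30)
  subjects <- sprintf("s%02d", 1:8)
  fake_phase <- function(ph) {
    segs <- unlist(lapply(subjects, function(sid)
      segment_track(generate_session(study_compositions()$before,
                                     duration_s = 100, subject_id = sid,
                                     phase = ph), 5)), recursive = FALSE)
    build_feature_matrix(segs)
  }
  fb <- fake_phase("before"); fa <- fake_phase("after")
  fd <- function(ph) data.frame(subject_id = rep(subjects, each = 2),
                                D = runif(16, 1.3, 1.7), phase = ph)
  lab <- function(fm) data.frame(subject_id = fm$subject_id,
                                 pattern = sample(names(pattern_archetypes()),
                                                  nrow(fm), replace = TRUE))
  rep_ <- compare_phases(fb, fa, fd("before"), fd("after"), lab(fb), lab(fa))
  expect_s3_class(rep_, "phase_report")
  expect_equal(nrow(rep_$parameters), 7L)
  expect_equal(nrow(rep_$patterns), 6L)
  # identically generated phases: moderate t values, percentages sum to 100
  expect_true(all(abs(rep_$patterns$t) < 10))
  sums <- tapply(rep_$pattern_percentages$percentage,
                 list(rep_$pattern_percentages$subject_id,
                      rep_$pattern_percentages$phase), sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # subject mismatch is refused
  fa_bad <- fa[fa$subject_id != "s01", ]
  expect_error(compare_phases(fb, fa_bad, fd("before"), fd("after"),
                              lab(fb), lab(fa)), "subject sets differ")

  # JSON export round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fractal$t, rep_$fractal$t, tolerance = 1e-9)
})

test_that("a planted composition shift is detected with the expected signs", {
  set.seed(50)
  comps <- study_compositions()
  study <- default_study(seed = 60, duration_s = 300, subjects = 6)
  lab_of <- function(tracks) do.call(rbind, lapply(tracks, function(tr)
    data.frame(subject_id = tr$subject_id, pattern = truth_labels(tr)$pattern)))
  fm_of <- function(tracks) do.call(rbind, lapply(tracks, function(tr)
    build_feature_matrix(segment_track(tr, 5))))
  fd_of <- function(tracks, ph) data.frame(
    subject_id = names(tracks), D = runif(length(tracks), 1.4, 1.6), phase = ph)
  rep_ <- compare_phases(fm_of(study$before), fm_of(study$after),
                         fd_of(study$before, "before"), fd_of(study$after, "after"),
                         lab_of(study$before), lab_of(study$after))
  p1 <- rep_$patterns[rep_$patterns$endpoint == "P1", ]
  p6 <- rep_$patterns[rep_$patterns$endpoint == "P6", ]
  expect_gt(p1$t, 0)             # P1 share falls after treatment
  expect_lt(p6$t, 0)             # P6 share rises
  expect_gt(p1$mean_before, p1$mean_after)
  expect_lt(p6$mean_before, p6$mean_after)
})
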