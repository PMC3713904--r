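nonwear_eps <- function(mask) {
  mask$episodes[mask$episodes$state == "nonwear", , drop = FALSE]
}

test_that("nonwear needs at least 40 consecutive near-zero minutes", {
  flank <- rep(100, 10)
  for (len in c(39L, 40L, 41L)) {
    s <- make_series(c(flank, rep(0, len), flank), unit = "counts")
    eps <- nonwear_eps(detect_nonwear(s))
    if (len < 40) {
      expect_identical(nrow(eps), 0L)
    } else {
      expect_identical(nrow(eps), 1L)
      expect_identical(eps$length, len)
    }
  }

  # a g/min series sitting just under 0.3 g for an hour is nonwear
  g <- make_series(rep(0.29, 60), unit = "g")
  expect_identical(nonwear_eps(detect_nonwear(g))$length, 60L)
  # ... and exactly 0.3 g is movement, the bound is strict
  g2 <- make_series(rep(0.30, 60), unit = "g")
  expect_identical(nrow(nonwear_eps(detect_nonwear(g2))), 0L)
  # counts at exactly 0 only
  c1 <- make_series(c(rep(100, 5), rep(1, 45), rep(100, 5)),
                    unit = "counts")
  expect_identical(nrow(nonwear_eps(detect_nonwear(c1))), 0L)
})

test_that("one supra-threshold minute splits a run; missing minutes break runs", {
  s <- make_series(c(rep(0, 40), 500, rep(0, 40)), unit = "counts")
  eps <- nonwear_eps(detect_nonwear(s))
  expect_identical(nrow(eps), 2L)
  expect_identical(eps$length, c(40L, 40L))

  # 39 + interruption + 39: neither half reaches the floor
  s2 <- make_series(c(rep(0, 39), 500, rep(0, 39)), unit = "counts")
  expect_identical(nrow(nonwear_eps(detect_nonwear(s2))), 0L)

  # a not-recorded minute also breaks the run
  s3 <- make_series(c(rep(0, 39), NA, rep(0, 39)), unit = "counts")
  m3 <- detect_nonwear(s3)
  expect_identical(nrow(nonwear_eps(m3)), 0L)
  expect_identical(as.character(m3$state[40]), "not_recorded")
})

test_that("wear mask states partition time, detection is idempotent-stable and monotone in min_run", {
  set.seed(41)
  vals <- sample(c(0, 0, 0, 50, 200, NA), 600, replace = TRUE)
  s <- make_series(vals, unit = "counts")
  m <- detect_nonwear(s)
  expect_identical(length(m$state), length(s))
  expect_identical(sum(table(m$state)), 600L)
  expect_identical(sum(m$episodes$length), 600L)
  # same series, same answer
  expect_identical(detect_nonwear(s)$state, m$state)
  # appending not-recorded minutes leaves earlier states untouched
  s_ext <- make_series(c(vals, rep(NA, 120)), unit = "counts")
  expect_identical(as.character(detect_nonwear(s_ext)$state[1:600]),
                   as.character(m$state))
  # lowering min_run never decreases nonwear minutes
  nw <- function(mr) sum(detect_nonwear(s, min_run = mr)$state == "nonwear")
  runs <- vapply(c(10, 20, 40, 80), nw, 1L)
  expect_true(all(diff(runs) <= 0))

  # a g-style fractional threshold on a counts series is refused
  expect_error(detect_nonwear(s, zero_threshold = 0.3), "counts/min")
})

test_that("usability summary implements the valid-day and valid-assessment rules", {
  # five full days worn continuously
  s <- make_series(rep(100, 5 * 1440), unit = "counts")
  u <- usability_summary(s, detect_nonwear(s))
  expect_identical(u$days_recorded, 5L)
  expect_identical(u$n_valid_days, 5L)
  expect_true(u$valid_assessment)
  expect_equal(u$recorded_hours_per_recorded_day, 24)
  expect_equal(u$pct_worn_of_recorded, 100)

  # two days of 11 worn hours, everything else unrecorded: not valid
  day <- c(rep(100, 11 * 60), rep(NA, 1440 - 11 * 60))
  s2 <- make_series(c(day, day, rep(NA, 3 * 1440)), unit = "counts")
  u2 <- usability_summary(s2, detect_nonwear(s2))
  expect_identical(u2$days_recorded, 2L)
  expect_identical(u2$n_valid_days, 2L)
  expect_false(u2$valid_assessment)

  # worn minutes never exceed recorded minutes; percentage is consistent
  s3 <- make_series(c(rep(0, 300), rep(80, 500), rep(NA, 640)),
                    unit = "counts")
  u3 <- usability_summary(s3, detect_nonwear(s3))
  expect_lte(u3$worn_minutes, u3$recorded_minutes)
  expect_equal(u3$pct_worn_of_recorded,
               100 * u3$worn_minutes / u3$recorded_minutes)

  # the recorded-time variant of the valid-day rule is switchable
  u4 <- usability_summary(s3, detect_nonwear(s3),
                          valid_day_basis = "recorded")
  expect_identical(u4$n_valid_days, 1L)
  expect_identical(u3$n_valid_days, 0L)
})

test_that("usability comparison reports tie-corrected Kruskal-Wallis H with group medians", {
  mk <- function(v) {
    df <- data.frame(matrix(rep(v, 7), ncol = 7))
    names(df) <- c("days_recorded", "recorded_minutes", "worn_minutes",
                   "recorded_hours_per_recorded_day",
                   "worn_hours_per_recorded_day",
                   "pct_worn_of_recorded", "n_valid_days")
    df
  }
  # identical groups: degenerate, reported as H = 0, p = 1
  same <- compare_usability(mk(c(4, 4, 4)), mk(c(4, 4, 4)))
  expect_true(all(same$H == 0))
  expect_true(all(same$p == 1))

  # hand-computed rank statistic for {1,2,3} vs {10,11,12}
  two <- compare_usability(mk(c(1, 2, 3)), mk(c(10, 11, 12)),
                           labels = c("a", "b"))
  expect_equal(unique(two$H), oracle_kruskal_h(list(1:3, 10:12)),
               tolerance = 1e-12)
  expect_equal(unique(two$H), 27 / 7, tolerance = 1e-12)
  expect_equal(two$median[two$group == "b" &
                            two$metric == "days_recorded"], 11)

  # three groups, with ties, against the tie-corrected oracle
  g1 <- c(3, 5, 5, 9); g2 <- c(5, 8, 12); g3 <- c(1, 2, 14, 14)
  three <- compare_usability(mk(g1), mk(g2), mk(g3))
  expect_equal(unique(three$H), oracle_kruskal_h(list(g1, g2, g3)),
               tolerance = 1e-10)
  expect_identical(unique(three$df), 2L)
})
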