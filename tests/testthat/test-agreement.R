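test_that("concordance matches the direct-formula oracle and penalizes location shift", {
  x <- c(12.1, 15.3, 9.8, 20.4, 17.7, 11.2, 14.9, 19.1, 10.5, 16.6)
  expect_equal(ccc(x, x)$estimate, 1, tolerance = 1e-12)

  shifted <- ccc(x, x + 3)
  expect_lt(shifted$estimate, 1)
  expect_lt(shifted$estimate, abs(shifted$r))

  set.seed(60)
  y <- 0.8 * x + rnorm(10, 2, 1.5)
  expect_equal(ccc(x, y)$estimate, oracle_ccc(x, y), tolerance = 1e-12)

  expect_error(ccc(rep(1, 5), rep(2, 5)), "both inputs constant")
  expect_error(ccc(1:2, 1:2), "at least 3")

  # CCC equals Pearson when means and variances agree
  xe <- c(1, 2, 3, 4, 5); ye <- c(2, 1, 3, 5, 4)
  got <- ccc(xe, ye)
  expect_equal(got$estimate, got$r, tolerance = 1e-12)

  # confidence interval is a proper interval around the estimate
  expect_true(shifted$ci[1] < shifted$estimate &&
                shifted$estimate < shifted$ci[2])
})

test_that("concordance approximates the between-subject variance share on two-level data", {
  set.seed(61)
  n <- 3000; sb <- 2; sm <- 1
  mu <- rnorm(n, 5, sb)
  x <- mu + rnorm(n, 0, sm)
  y <- mu + rnorm(n, 0, sm)
  expect_equal(ccc(x, y)$estimate, sb^2 / (sb^2 + sm^2),
               tolerance = 0.03)
})

test_that("Spearman correlation handles ties like hand ranking and has a sane null", {
  x <- 1:8
  expect_equal(spearman_with_ci(x, c(2, 3, 5, 9, 12, 20, 21, 30))$rho, 1)

  xt <- c(1.0, 2.0, 2.0, 3.5, 4.0, 5.5, 6.0, 7.2)
  yt <- c(3.1, 2.9, 4.4, 4.4, 6.0, 5.1, 8.0, 7.5)
  expect_equal(spearman_with_ci(xt, yt)$rho, oracle_spearman(xt, yt),
               tolerance = 1e-12)

  expect_error(spearman_with_ci(rep(2, 8), 1:8), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")

  set.seed(62)
  got <- spearman_with_ci(runif(10000), runif(10000))
  expect_lt(abs(got$rho), 0.05)
  expect_true(got$ci[1] < got$rho && got$rho < got$ci[2])
})

test_that("Bland-Altman reports differences, limits and proportional bias correctly", {
  x <- c(3.2, 4.4, 6.8, 5.1, 7.7, 2.9)
  ident <- bland_altman(x, x)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$bias_slope, 0, tolerance = 1e-12)
  expect_false(ident$bias_significant)

  # constant offset: zero-width limits at the offset
  const <- bland_altman(x + 1.25, x)
  expect_equal(const$mean_diff, 1.25, tolerance = 1e-12)
  expect_equal(const$loa, c(1.25, 1.25), tolerance = 1e-12)

  # an injected proportional bias of 0.5 is detected at n = 500
  set.seed(63)
  m <- runif(500, 0, 10)
  d <- 0.5 * m + rnorm(500, 0, 0.5)
  ba <- bland_altman(m + d / 2, m - d / 2)
  expect_true(ba$bias_significant)
  expect_true(ba$bias_slope_ci[1] < 0.5 && 0.5 < ba$bias_slope_ci[2])

  expect_error(bland_altman(1:2, 2:3), "at least 3")

  # gaussian differences: the limits hold about 95% of points
  set.seed(64)
  xg <- rnorm(1000, 10, 2); yg <- xg - rnorm(1000, 0.2, 1)
  bg <- bland_altman(xg, yg)
  dd <- xg - yg
  cover <- mean(dd >= bg$loa[1] & dd <= bg$loa[2])
  expect_lt(abs(cover - 0.95), 0.025)

  # all statistics invariant under a common permutation of pairs
  set.seed(65)
  p <- sample(1000)
  bp <- bland_altman(xg[p], yg[p])
  expect_equal(bp$mean_diff, bg$mean_diff)
  expect_equal(bp$loa, bg$loa)
  expect_equal(bp$bias_slope, bg$bias_slope)
  expect_equal(ccc(xg[p], yg[p])$estimate, ccc(xg, yg)$estimate)
  expect_equal(spearman_with_ci(xg[p], yg[p])$rho,
               spearman_with_ci(xg, yg)$rho)
})

mk_participant <- function(id, counts, joint = NULL) {
  ag <- freedson_actigraph_model()
  g <- (counts - 0) / 500
  if (is.null(joint)) joint <- rep(TRUE, length(counts))
  mets <- predict_mets(ag, counts)
  list(id = id, phone_vt = g, ref_vt = counts,
       mets_phone = mets, mets_ref = mets, joint = joint)
}

test_that("minute-level comparison is perfect under exact linear agreement and logs exclusions", {
  set.seed(66)
  parts <- lapply(1:5, function(i)
    mk_participant(paste0("P", i), runif(400, 0, 4000)))
  parts[[6]] <- mk_participant("P6", runif(400, 0, 4000),
                               joint = rep(FALSE, 400))
  expect_message(cmp <- compare_minutes(parts), "P6")
  expect_identical(cmp$excluded, "P6")
  expect_equal(cmp$vt$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(cmp$reports$active_pct$ccc, 1, tolerance = 1e-12)
  expect_equal(cmp$reports$active_pct$mean_difference, 0,
               tolerance = 1e-12)
  expect_equal(cmp$reports$mean_mets$ccc, 1, tolerance = 1e-12)
  # within-class intensities agree exactly under identity
  expect_equal(cmp$class_intensity$mean_phone,
               cmp$class_intensity$mean_ref, tolerance = 1e-12)
  # per-class n values sum to the compared minutes
  expect_identical(sum(cmp$class_intensity$n), 5L * 400L)
})

test_that("day-level comparison uses only days valid on both devices", {
  day_min <- 1440
  mk_day_part <- function(id, phone_short_day) {
    mets <- rep(c(1.3, 2, 4), length.out = 2 * day_min)
    worn_ref <- rep(TRUE, 2 * day_min)
    worn_ph <- worn_ref
    if (phone_short_day)  # second phone day has < 10 h of wear
      worn_ph[(day_min + 1):(2 * day_min)] <-
        c(rep(TRUE, 500), rep(FALSE, day_min - 500))
    day <- rep(c("d1", "d2"), each = day_min)
    list(id = id,
         phone = list(day = day, worn = worn_ph, mets = mets),
         ref = list(day = day, worn = worn_ref, mets = mets))
  }
  parts <- list(mk_day_part("A", FALSE), mk_day_part("B", TRUE))
  got <- compare_days(parts)
  expect_false(got$empty)
  expect_identical(got$n_days, 3L)  # B's short phone day dropped
  expect_equal(got$reports$active$mean_difference, 0, tolerance = 1e-12)

  # one device with no valid day at all: empty report flag
  none <- list(list(id = "C",
                    phone = list(day = rep("d1", day_min),
                                 worn = rep(FALSE, day_min),
                                 mets = rep(2, day_min)),
                    ref = list(day = rep("d1", day_min),
                               worn = rep(TRUE, day_min),
                               mets = rep(2, day_min))))
  expect_true(compare_days(none)$empty)
})
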