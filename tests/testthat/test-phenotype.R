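test_that("luciferase normalization anchors the reference at 1", {
  rec <- tibble::tibble(condition = rep(c("miR-C", "miR-16"), each = 3),
                        well = 1:6,
                        firefly = c(100, 100, 100, 50, 50, 50),
                        renilla = rep(10, 6))
  res <- normalize_luciferase(rec, "miR-C")
  expect_equal(res$relative_activity[res$condition == "miR-C"], 1)
  expect_equal(res$relative_activity[res$condition == "miR-16"], 0.5)

  # identical wells everywhere: every condition is 1
  rec2 <- dplyr::mutate(rec, firefly = 80, renilla = 20)
  expect_equal(normalize_luciferase(rec2, "miR-C")$relative_activity,
               c(1, 1))
})

test_that("luciferase normalization is invariant to channel rescalings", {
  set.seed(5)
  rec <- tibble::tibble(condition = rep(c("ref", "a", "b"), each = 4),
                        well = 1:12,
                        firefly = runif(12, 50, 150),
                        renilla = runif(12, 5, 15))
  base <- normalize_luciferase(rec, "ref")
  scaled_f <- dplyr::mutate(rec, firefly = firefly * 7)
  scaled_r <- dplyr::mutate(rec, renilla = renilla * 0.3)
  expect_equal(normalize_luciferase(scaled_f, "ref")$relative_activity,
               base$relative_activity)
  expect_equal(normalize_luciferase(scaled_r, "ref")$relative_activity,
               base$relative_activity)

  # zero-Renilla wells are excluded with a message
  rec$renilla[1] <- 0
  expect_message(normalize_luciferase(rec, "ref"), "non-positive Renilla")
  rec$renilla[rec$condition == "ref"] <- 0
  expect_error(suppressMessages(normalize_luciferase(rec, "ref")),
               "no usable wells")
})

test_that("4PL fit recovers a generated standard curve", {
  truth <- c(a = 0.05, b = 1.2, c = 120, d = 2.4)
  fourpl <- function(x) truth[["d"]] + (truth[["a"]] - truth[["d"]]) /
    (1 + (x / truth[["c"]])^truth[["b"]])
  standards <- tibble::tibble(concentration = c(0, 10, 30, 90, 270, 810,
                                                2430),
                              absorbance = fourpl(c(0, 10, 30, 90, 270, 810,
                                                    2430)))
  curve <- fit_standard_curve(standards)
  expect_equal(unname(curve$coef[names(truth)]), unname(truth),
               tolerance = 0.01)

  # absorbance exactly at a standard recovers that standard's concentration
  samples <- tibble::tibble(sample_id = "s1",
                            absorbance = fourpl(c(90, 90)))
  res <- elisa_correct(samples, curve)
  expect_equal(res$concentration, 90, tolerance = 1e-6)
  expect_equal(res$flag, "ok")
  expect_equal(res$n_measures, 2L)

  # out-of-range absorbance is flagged, never extrapolated
  high <- tibble::tibble(sample_id = "hot", absorbance = fourpl(2430) * 1.2)
  res_high <- elisa_correct(high, curve)
  expect_equal(res_high$flag, "out_of_range")
  expect_true(is.na(res_high$concentration))

  expect_error(fit_standard_curve(standards[1:3, ]), "at least 4")
})

test_that("duplicate averaging happens after inversion by default", {
  truth <- c(a = 0, b = 2, c = 100, d = 2)
  fourpl <- function(x) truth[["d"]] + (truth[["a"]] - truth[["d"]]) /
    (1 + (x / truth[["c"]])^truth[["b"]])
  standards <- tibble::tibble(concentration = c(5, 25, 100, 400, 1600),
                              absorbance = fourpl(c(5, 25, 100, 400, 1600)))
  curve <- fit_standard_curve(standards)
  # the 4PL is nonlinear, so mean(invert) != invert(mean)
  samples <- tibble::tibble(sample_id = "s", absorbance = fourpl(c(50, 200)))
  after <- elisa_correct(samples, curve, average = "concentration")
  before <- elisa_correct(samples, curve, average = "absorbance")
  expect_equal(after$concentration, 125, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(after$concentration, before$concentration)))
})

test_that("wound T1/2 follows the first-crossing interpolation rule", {
  # exact grid point
  s1 <- tibble::tibble(condition = "c", time_h = c(0, 4, 8, 12),
                       gap_area = c(100, 75, 50, 25))
  expect_equal(wound_t_half(s1)$t_half, 8)
  # interpolation between brackets
  s2 <- tibble::tibble(condition = "c", time_h = c(0, 4, 8),
                       gap_area = c(100, 60, 40))
  expect_equal(wound_t_half(s2)$t_half, 4 + 10 / 5)
  # short decreasing series projected at most one interval past the end
  s3 <- tibble::tibble(condition = "c", time_h = c(0, 10),
                       gap_area = c(100, 60))
  r3 <- wound_t_half(s3)
  expect_equal(r3$t_half, 12.5)
  expect_equal(r3$method, "extrapolated")
  expect_false(r3$censored)
  # plateau well above half: censored at the last time
  s4 <- tibble::tibble(condition = "c", time_h = c(0, 4, 8, 12),
                       gap_area = c(100, 70, 65, 62))
  r4 <- wound_t_half(s4)
  expect_true(r4$censored)
  expect_equal(r4$t_half, 12)
  # first-crossing rule under non-monotone noise
  s5 <- tibble::tibble(condition = "c", time_h = 0:4,
                       gap_area = c(100, 45, 60, 30, 20))
  expect_equal(wound_t_half(s5)$t_half, 0 + (50 - 100) / (45 - 100))
})

test_that("wound T1/2 dilates linearly with the time axis", {
  sim <- sim_wound(true_thalf = 9, model = "logistic", dt = 0.75,
                   horizon = 27, noise_cv = 0.05, seed = 8)
  t1 <- wound_t_half(sim$series)$t_half
  dilated <- dplyr::mutate(sim$series, time_h = time_h * 3)
  expect_equal(wound_t_half(dilated)$t_half, 3 * t1)
})

test_that("noise-free generated wounds recover the planted T1/2", {
  for (th in c(6, 12, 18)) {
    lin <- sim_wound(true_thalf = th, model = "linear", dt = 1,
                     horizon = 3 * th, noise_cv = 0)
    expect_equal(wound_t_half(lin$series)$t_half, th)
    logi <- sim_wound(true_thalf = th, model = "logistic", dt = 1,
                      horizon = 3 * th, noise_cv = 0)
    expect_lte(abs(wound_t_half(logi$series)$t_half - th), 0.5)
  }
})

test_that("linear association matches the closed-form normal equations", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = 2 * c(1, 2, 3, 4, 5))
  g <- glance(linear_association(df, x, y))
  expect_equal(g$slope, 2)
  expect_equal(g$r_squared, 1)

  df2 <- tibble::tibble(x = 1:6, y = rep(3, 6))
  g2 <- glance(linear_association(df2, x, y))
  expect_equal(g2$slope, 0)
  expect_equal(g2$r_squared, 0)

  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(5 + i)
    y <- 1 + 0.5 * x + rnorm(length(x))
    g <- glance(linear_association(tibble::tibble(x = x, y = y), x, y))
    o <- ols_oracle(x, y)
    expect_equal(g$slope, o$slope, tolerance = 1e-10)
    expect_equal(g$slope_se, o$slope_se, tolerance = 1e-10)
    expect_equal(g$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(g$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("linear association applies threshold subsetting and censoring", {
  df <- tibble::tibble(hgf = c(0.2, 0.5, 1.5, 2, 3, 4),
                       resp = c(9, 9, 1.5, 2, 3, 4),
                       censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  fit <- suppressMessages(
    linear_association(df, hgf, resp, x_threshold = 1))
  g <- glance(fit)
  expect_equal(g$n, 3)            # x > 1, censored row dropped
  expect_equal(g$slope, 1, tolerance = 1e-10)
  expect_error(linear_association(df[1:2, ], hgf, resp), "at least 3")
})
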