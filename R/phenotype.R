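#' Read a dual-luciferase well table
#'
#' CSV with columns `condition, well, firefly, renilla` (relative light
#' units).
#' @param path Path to a CSV file.
#' @return A tibble of luciferase records.
#' @export
read_luciferase <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(rec, c("condition", "well", "firefly", "renilla"),
                "Luciferase table")
  tibble::as_tibble(rec)
}

#' Renilla-normalized relative luciferase activity
#'
#' Computes per-well firefly/Renilla ratios (Renilla controls for
#' transfection efficiency), averages them per condition, and expresses each
#' condition relative to the reference condition's mean ratio (reference
#' activity = 1). Wells with non-positive Renilla signal are excluded with a
#' message.
#'
#' @param records A luciferase table (see [read_luciferase()]).
#' @param reference_condition Condition used as the denominator.
#' @return A tibble `condition, n_wells, mean_ratio, sd_ratio,
#'   relative_activity, relative_sd`.
#' @export
normalize_luciferase <- function(records, reference_condition) {
  check_columns(records, c("condition", "firefly", "renilla"),
                "Luciferase table")
  bad <- which(!(records$renilla > 0))
  if (length(bad) > 0) {
    inform(sprintf("Excluding %d well(s) with non-positive Renilla signal.",
                   length(bad)))
    records <- records[-bad, , drop = FALSE]
  }
  if (!reference_condition %in% records$condition) {
    abort(sprintf("Reference condition '%s' has no usable wells.",
                  reference_condition))
  }
  per_cond <- records |>
    dplyr::mutate(ratio = .data$firefly / .data$renilla) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_wells = dplyr::n(),
                     mean_ratio = mean(.data$ratio),
                     sd_ratio = stats::sd(.data$ratio),
                     .groups = "drop")
  ref <- per_cond$mean_ratio[per_cond$condition == reference_condition]
  per_cond |>
    dplyr::mutate(relative_activity = .data$mean_ratio / ref,
                  relative_sd = .data$sd_ratio / ref)
}

#' Fit a four-parameter-logistic ELISA standard curve
#'
#' Fits `A(x) = d + (a - d) / (1 + (x / c)^b)` to standard concentrations and
#' absorbances by bounded iterative least squares (Levenberg-Marquardt),
#' initialized from the standards' extremes and log-mid concentration, and
#' checks that the fitted curve is monotone over the standards' range.
#'
#' @param standards Tibble with `concentration` and `absorbance` columns
#'   (at least 4 standards).
#' @return An object of class `elisa_curve`; supports [tidy()], [glance()],
#'   [predict()] and [autoplot()].
#' @export
fit_standard_curve <- function(standards) {
  check_columns(standards, c("concentration", "absorbance"),
                "Standards table")
  standards <- dplyr::arrange(tibble::as_tibble(standards),
                              .data$concentration)
  if (nrow(standards) < 4) abort("Need at least 4 standards for a 4PL fit.")
  if (any(standards$concentration < 0)) {
    abort("Standard concentrations must be non-negative.")
  }
  pos <- standards$concentration[standards$concentration > 0]
  fourpl <- function(p, x) {
    p[["d"]] + (p[["a"]] - p[["d"]]) / (1 + (x / p[["c"]])^p[["b"]])
  }
  start <- c(a = standards$absorbance[1],
             d = standards$absorbance[nrow(standards)],
             c = exp(mean(log(pos))), b = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) standards$absorbance - fourpl(p, standards$concentration),
    lower = c(-Inf, -Inf, 1e-12, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- fit$par
  if (abs(cf[["a"]] - cf[["d"]]) < 1e-12) {
    abort("Fitted standard curve is flat; cannot invert.")
  }
  # b > 0 and a != d make the 4PL strictly monotone on x > 0; record the
  # usable absorbance range from the fitted values at the standards.
  fitted_abs <- fourpl(cf, standards$concentration)
  dfree <- max(1, nrow(standards) - 4)
  vcov <- tryCatch(solve(fit$hessian) * fit$deviance / dfree,
                   error = function(e) matrix(NA_real_, 4, 4,
                                              dimnames = list(names(cf),
                                                              names(cf))))
  structure(list(fit = fit, coef = cf, vcov = vcov, standards = standards,
                 fourpl = fourpl,
                 sigma = sqrt(fit$deviance / dfree),
                 abs_range = range(fitted_abs)),
            class = "elisa_curve")
}

#' @export
print.elisa_curve <- function(x, ...) {
  cf <- x$coef
  cat(sprintf(
    "4PL ELISA standard curve: a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
    cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]]))
  cat(sprintf("Usable absorbance range: [%.4g, %.4g] (%d standards)\n",
              x$abs_range[1], x$abs_range[2], nrow(x$standards)))
  invisible(x)
}

#' @export
tidy.elisa_curve <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std_error = sqrt(diag(x$vcov)))
}

#' @export
glance.elisa_curve <- function(x, ...) {
  tibble::tibble(n_standards = nrow(x$standards),
                 sigma = x$sigma,
                 rss = x$fit$deviance)
}

#' @export
predict.elisa_curve <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$standards$concentration else
    newdata$concentration
  object$fourpl(object$coef, x)
}

#' @export
autoplot.elisa_curve <- function(object, ...) {
  std <- object$standards
  pos <- std$concentration[std$concentration > 0]
  grid <- tibble::tibble(concentration = exp(seq(log(min(pos) / 2),
                                                 log(max(pos) * 2),
                                                 length.out = 200)))
  grid$absorbance <- predict(object, grid)
  ggplot2::ggplot(std, ggplot2::aes(x = .data$concentration,
                                    y = .data$absorbance)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = "Absorbance",
                  title = "4PL standard curve") +
    ggplot2::theme_minimal()
}

invert_4pl <- function(cf, y) {
  # x = c * ((a - d)/(y - d) - 1)^(1/b)
  ratio <- (cf[["a"]] - cf[["d"]]) / (y - cf[["d"]]) - 1
  out <- rep(NA_real_, length(y))
  ok <- is.finite(ratio) & ratio >= 0
  out[ok] <- cf[["c"]] * ratio[ok]^(1 / cf[["b"]])
  out
}

#' Correct ELISA absorbances against a standard curve
#'
#' Converts raw sample absorbances to concentrations by inverse evaluation
#' of a 4PL standard curve. Duplicate measures of a sample are averaged
#' after inversion by default (average concentrations), or before
#' (`average = "absorbance"`). Absorbances outside the standards' fitted
#' range are flagged `out_of_range` and not extrapolated.
#'
#' @param samples Tibble with `sample_id` and `absorbance` columns.
#' @param standards Standards tibble (see [fit_standard_curve()]) or a
#'   prefitted `elisa_curve`.
#' @param average `"concentration"` (invert, then average duplicates) or
#'   `"absorbance"` (average duplicates, then invert).
#' @return A tibble `sample_id, n_measures, concentration, flag`
#'   (`flag` in `ok`/`out_of_range`), with the fitted curve in the
#'   `"curve"` attribute.
#' @export
elisa_correct <- function(samples, standards,
                          average = c("concentration", "absorbance")) {
  average <- match.arg(average)
  check_columns(samples, c("sample_id", "absorbance"), "Samples table")
  curve <- if (inherits(standards, "elisa_curve")) standards else
    fit_standard_curve(standards)
  rng <- curve$abs_range
  eps <- 1e-9 * diff(rng)
  in_range <- function(y) y >= rng[1] - eps & y <= rng[2] + eps

  if (average == "absorbance") {
    samples <- samples |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(n_measures = dplyr::n(),
                       absorbance = mean(.data$absorbance),
                       .groups = "drop")
    conc <- invert_4pl(curve$coef, samples$absorbance)
    out <- tibble::tibble(sample_id = samples$sample_id,
                          n_measures = samples$n_measures,
                          concentration = ifelse(in_range(samples$absorbance),
                                                 conc, NA_real_),
                          flag = ifelse(in_range(samples$absorbance), "ok",
                                        "out_of_range"))
  } else {
    per <- samples |>
      dplyr::mutate(ok = in_range(.data$absorbance),
                    conc = ifelse(.data$ok,
                                  invert_4pl(curve$coef, .data$absorbance),
                                  NA_real_))
    out <- per |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(n_measures = dplyr::n(),
                       concentration = if (all(.data$ok))
                         mean(.data$conc) else NA_real_,
                       flag = if (all(.data$ok)) "ok" else "out_of_range",
                       .groups = "drop")
  }
  attr(out, "curve") <- curve
  out
}

#' Read a wound-closure time series table
#'
#' CSV with columns `condition, time_h, gap_area`.
#' @param path Path to a CSV file.
#' @return A tibble of wound series records.
#' @export
read_wound_series <- function(path) {
  series <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(series, c("condition", "time_h", "gap_area"), "Wound series")
  tibble::as_tibble(series)
}

#' Half-closure time (T1/2) of wound gap-area series
#'
#' For each condition, T1/2 is the time at which the gap area first falls to
#' half of its initial value, located by linear interpolation between the
#' bracketing observations (first-crossing rule, so transient noise below
#' half counts as closure). A series that never reaches half closure is
#' handled in two steps: if its final segment is still decreasing and its
#' linear projection reaches half within one further sampling interval, the
#' projected time is reported with method `"extrapolated"`; otherwise the
#' series is censored at its last observation time.
#'
#' @param series A wound series tibble (`condition, time_h, gap_area`),
#'   at least 2 time points per condition, strictly increasing times.
#' @return A tibble `condition, t_half, censored, method, n_points`
#'   (`t_half` is the last observation time for censored series).
#' @export
wound_t_half <- function(series) {
  check_columns(series, c("condition", "time_h", "gap_area"), "Wound series")
  if (any(series$gap_area < 0)) abort("Gap areas must be non-negative.")
  series |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_h)
      t <- df$time_h
      a <- df$gap_area
      n <- length(t)
      if (n < 2) abort(sprintf("Condition %s has fewer than 2 time points.",
                               key$condition))
      if (any(diff(t) <= 0)) {
        abort(sprintf("Times must be strictly increasing (condition %s).",
                      key$condition))
      }
      target <- a[1] / 2
      hit <- which(a <= target)
      if (length(hit) > 0) {
        i <- hit[1]
        t_half <- if (i == 1) t[1] else if (a[i] == a[i - 1]) t[i] else
          t[i - 1] + (target - a[i - 1]) * (t[i] - t[i - 1]) /
            (a[i] - a[i - 1])
        return(tibble::tibble(t_half = t_half, censored = FALSE,
                              method = "interpolated", n_points = n))
      }
      slope <- (a[n] - a[n - 1]) / (t[n] - t[n - 1])
      if (slope < 0) {
        t_ext <- t[n] + (target - a[n]) / slope
        if (t_ext <= t[n] + (t[n] - t[n - 1])) {
          return(tibble::tibble(t_half = t_ext, censored = FALSE,
                                method = "extrapolated", n_points = n))
        }
      }
      tibble::tibble(t_half = t[n], censored = TRUE, method = "censored",
                     n_points = n)
    }) |>
    dplyr::ungroup()
}

#' Plot wound gap-closure time courses
#'
#' @param series A wound series tibble.
#' @param thalf Optional [wound_t_half()] output; uncensored T1/2 values are
#'   marked.
#' @return A ggplot object.
#' @export
plot_wound <- function(series, thalf = NULL) {
  check_columns(series, c("condition", "time_h", "gap_area"), "Wound series")
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_h,
                                            y = .data$gap_area,
                                            colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time (h)", y = "Gap area", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thalf)) {
    marks <- dplyr::filter(thalf, !.data$censored)
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$t_half, colour = .data$condition),
      linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' Ordinary-least-squares association between a concentration and a response
#'
#' Fits `y ~ x` by OLS and reports the slope with its standard error, the
#' intercept, and R squared — the "R², slope ± SE" summary used for, e.g.,
#' relating wound-closure T1/2 to the HGF concentration in conditioned
#' medium. An optional strict threshold restricts the fit to observations
#' with `x > x_threshold` (e.g. high-expressing samples only); censored
#' observations (a logical `censored` column) are excluded by default with a
#' message.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of predictor and response.
#' @param x_threshold Optional strict lower threshold applied to `x` before
#'   fitting.
#' @param drop_censored Exclude rows where a `censored` column is `TRUE`?
#' @return An object of class `linear_assoc`; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
linear_association <- function(data, x, y, x_threshold = NULL,
                               drop_censored = TRUE) {
  x_q <- enquo(x)
  y_q <- enquo(y)
  df <- tibble::tibble(x = dplyr::pull(data, !!x_q),
                       y = dplyr::pull(data, !!y_q))
  if (drop_censored && "censored" %in% names(data)) {
    n_cens <- sum(data$censored)
    if (n_cens > 0) {
      inform(sprintf("Excluding %d censored observation(s).", n_cens))
      df <- df[!data$censored, , drop = FALSE]
    }
  }
  if (!is.null(x_threshold)) df <- df[df$x > x_threshold, , drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) abort("Need at least 3 observations after subsetting.")
  fit <- lm(y ~ x, data = df)
  structure(list(fit = fit, data = df, n = nrow(df),
                 x_name = as_name(x_q), y_name = as_name(y_q),
                 x_threshold = x_threshold),
            class = "linear_assoc")
}

#' @export
print.linear_assoc <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Linear association %s ~ %s (n = %d%s)\n", x$y_name, x$x_name,
              g$n, if (!is.null(x$x_threshold))
                sprintf(", %s > %g", x$x_name, x$x_threshold) else ""))
  cat(sprintf("R^2 = %.4f, slope = %.4g ± %.4g\n",
              g$r_squared, g$slope, g$slope_se))
  invisible(x)
}

lm_summary_quiet <- function(fit) {
  # exact fixtures legitimately produce zero residuals; silence summary.lm's
  # "essentially perfect fit" note
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' @export
tidy.linear_assoc <- function(x, ...) {
  s <- lm_summary_quiet(x$fit)$coefficients
  tibble::tibble(term = c("intercept", x$x_name),
                 estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.linear_assoc <- function(x, ...) {
  s <- lm_summary_quiet(x$fit)
  # a constant response has no variance to explain: define R^2 = 0 rather
  # than the 0/0 the usual formula produces
  r2 <- if (stats::var(x$data$y) == 0) 0 else s$r.squared
  tibble::tibble(slope = s$coefficients[2, 1],
                 slope_se = s$coefficients[2, 2],
                 intercept = s$coefficients[1, 1],
                 r_squared = r2,
                 n = x$n)
}

#' @export
autoplot.linear_assoc <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#3366aa") +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      subtitle = sprintf("R² = %.4f, slope = %.4g ± %.4g",
                         g$r_squared, g$slope, g$slope_se)) +
    ggplot2::theme_minimal()
}
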