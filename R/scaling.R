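#' Fit a log-log abundance-versus-rate scaling relationship
#'
#' Ordinary least squares of `log10(abundance)` on `log10(rate)` for one
#' chaperone class, the standard way allometric exponents are estimated
#' from cross-species abundance tables (abundance against basal metabolic
#' rate, or against synthesis rate). Flagged outliers (e.g. a single
#' discordant species) are excluded by default but recorded. Reduced major
#' axis regression is available behind `method = "rma"` for users who
#' prefer symmetric error treatment; OLS is the default since reported
#' per-class R-squared values treat rate as the independent variable.
#'
#' @param data A data frame with columns `sample_id`, `rate`,
#'   `chaperone_class`, `abundance` and optionally `outlier_flag`.
#' @param class_label Chaperone class to fit; `NULL` (default) uses all
#'   rows (requires a single class present).
#' @param exclude_outliers Drop rows with `outlier_flag = TRUE` (default
#'   `TRUE`).
#' @param method `"ols"` (default) or `"rma"`.
#' @param detect_outliers If `TRUE`, additionally flag points with
#'   studentized residual `|t| > detect_threshold` and refit without them
#'   (off by default; outliers are normally user-flagged).
#' @param detect_threshold Studentized-residual cutoff (default 3).
#' @return An object of class `slope_fit`: slope and intercept (log10
#'   scale), `r_squared`, `n_used`, `excluded_ids`, the underlying data
#'   and, for OLS, the `lm` fit. Use [tidy()] / [glance()] to extract
#'   tibbles and [autoplot()] to plot.
#' @examples
#' tab <- gen_abundance_table(generator_config(seed = 1))
#' fit <- fit_loglog(tab)
#' tidy(fit)
#' @export
fit_loglog <- function(data, class_label = NULL, exclude_outliers = TRUE,
                       method = c("ols", "rma"), detect_outliers = FALSE,
                       detect_threshold = 3) {
  method <- match.arg(method)
  data <- validate_abundance_table(data)
  if (!is.null(class_label)) {
    data <- dplyr::filter(data, .data$chaperone_class == class_label)
    if (nrow(data) == 0)
      abort(sprintf("no rows with chaperone_class == '%s'", class_label))
  } else {
    cls <- unique(data$chaperone_class)
    if (length(cls) > 1)
      abort("multiple chaperone classes present; supply `class_label`.")
    class_label <- cls
  }
  excluded <- character(0)
  if (exclude_outliers) {
    excluded <- data$sample_id[data$outlier_flag]
    used <- dplyr::filter(data, !.data$outlier_flag)
  } else {
    used <- data
  }
  if (nrow(used) < 3)
    abort("need at least 3 non-excluded points to fit a slope.")

  do_fit <- function(d) {
    x <- log10(d$rate); y <- log10(d$abundance)
    if (method == "ols") {
      fit <- lm(y ~ x)
      # R^2 computed directly so exact power laws do not warn
      tss <- sum((y - mean(y))^2)
      r2 <- if (tss == 0) NA_real_
            else 1 - sum(stats::residuals(fit)^2) / tss
      list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
           r_squared = r2, lm = fit)
    } else {
      r <- stats::cor(x, y)
      slope <- sign(r) * stats::sd(y) / stats::sd(x)
      list(slope = slope, intercept = mean(y) - slope * mean(x),
           r_squared = r^2, lm = NULL)
    }
  }
  res <- do_fit(used)
  if (detect_outliers && method == "ols") {
    t_stud <- stats::rstudent(res$lm)
    # a gross outlier against an otherwise perfect fit makes the deleted
    # residual variance zero and rstudent NaN: treat that as |t| = Inf
    degenerate <- is.nan(t_stud) &
      abs(stats::residuals(res$lm)) > 1e-8
    bad <- (!is.na(t_stud) & abs(t_stud) > detect_threshold) | degenerate
    if (any(bad) && sum(!bad) >= 3) {
      excluded <- c(excluded, used$sample_id[bad])
      used <- used[!bad, , drop = FALSE]
      res <- do_fit(used)
    }
  }
  structure(
    list(chaperone_class = class_label, slope = res$slope,
         intercept = res$intercept, r_squared = res$r_squared,
         n_used = nrow(used), excluded_ids = excluded, method = method,
         fit = res$lm, data = data),
    class = "slope_fit"
  )
}

#' Fit every chaperone class in an abundance table
#'
#' Convenience wrapper over [fit_loglog()]: one fit per class, returned as
#' a tidy tibble.
#'
#' @inheritParams fit_loglog
#' @return A tibble with one row per class: `chaperone_class`, `slope`,
#'   `intercept`, `r_squared`, `n_used`, `n_excluded`.
#' @export
fit_scaling <- function(data, exclude_outliers = TRUE,
                        method = c("ols", "rma")) {
  method <- match.arg(method)
  data <- validate_abundance_table(data)
  purrr::map_dfr(sort(unique(data$chaperone_class)), function(cl)
    tidy(fit_loglog(data, cl, exclude_outliers = exclude_outliers,
                    method = method)))
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> %s (%s): slope = %.3f, intercept = %.3f, R^2 = %.3f, n = %d\n",
              x$chaperone_class, toupper(x$method), x$slope, x$intercept,
              x$r_squared, x$n_used))
  if (length(x$excluded_ids))
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(
    chaperone_class = x$chaperone_class, slope = x$slope,
    intercept = x$intercept, r_squared = x$r_squared, n_used = x$n_used,
    n_excluded = length(x$excluded_ids)
  )
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_used = x$n_used,
                 n_excluded = length(x$excluded_ids), method = x$method)
}

#' Average scaling exponent over several fits
#'
#' Unweighted arithmetic mean of fitted slopes, the summary used when
#' asking whether a family of chaperones shares a common scaling with
#' metabolic rate.
#'
#' @param fits A list of `slope_fit` objects, a data frame with a `slope`
#'   column, or a numeric vector of slopes.
#' @return The mean slope (scalar).
#' @examples
#' average_exponent(c(-0.18, -0.59, -0.19, -0.42))
#' @export
average_exponent <- function(fits) {
  slopes <- if (is.numeric(fits)) {
    fits
  } else if (is.data.frame(fits)) {
    fits$slope
  } else if (inherits(fits, "slope_fit")) {
    fits$slope
  } else if (is.list(fits)) {
    vapply(fits, function(f) {
      if (inherits(f, "slope_fit")) f$slope
      else if (is.numeric(f)) as.numeric(f)
      else abort("list elements must be slope_fit objects or numbers.")
    }, numeric(1))
  } else {
    abort("`fits` must be slope_fit objects, a data frame, or numbers.")
  }
  if (length(slopes) == 0) abort("no slopes supplied.")
  mean(slopes)
}

#' Compare a fitted slope with a predicted scaling exponent
#'
#' @param fit A `slope_fit` (or a bare numeric slope).
#' @param predicted_slope The model-predicted exponent (e.g. -1 for
#'   holdases at slow growth, 0 for foldases).
#' @param band Half-width of the agreement band (default 0.25, symmetric).
#' @return A one-row tibble: `chaperone_class`, `slope`, `predicted`,
#'   `difference`, `within_band`.
#' @export
compare_to_prediction <- function(fit, predicted_slope, band = 0.25) {
  slope <- if (inherits(fit, "slope_fit")) fit$slope else as.numeric(fit)
  cl <- if (inherits(fit, "slope_fit")) fit$chaperone_class else NA_character_
  diff <- slope - predicted_slope
  tibble::tibble(chaperone_class = cl, slope = slope,
                 predicted = predicted_slope, difference = diff,
                 within_band = abs(diff) <= band)
}

# shared validation of the tidy abundance-table schema
validate_abundance_table <- function(data, require_positive = TRUE) {
  if (!is.data.frame(data)) abort("abundance table must be a data frame.")
  needed <- c("sample_id", "rate", "chaperone_class", "abundance")
  missing <- setdiff(needed, names(data))
  if (length(missing))
    abort(paste0("abundance table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (!("outlier_flag" %in% names(data))) data$outlier_flag <- FALSE
  data$outlier_flag[is.na(data$outlier_flag)] <- FALSE
  if (!is.numeric(data$rate) || !is.numeric(data$abundance))
    abort("`rate` and `abundance` must be numeric.")
  if (require_positive && (any(data$rate <= 0) || any(data$abundance <= 0)))
    abort("`rate` and `abundance` must be > 0 (log-transformable).")
  tibble::as_tibble(data)
}
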