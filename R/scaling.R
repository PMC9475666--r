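# Allometric scaling: log10-log10 OLS fits and slope comparisons.

#' Log-log ordinary least squares regression
#'
#' Fits `log10(y) ~ log10(x)` by OLS and returns the slope (the allometric
#' exponent), intercept, R^2, the two-sided p-value of the slope, and n.
#'
#' @param x,y strictly positive numeric vectors of equal length, n >= 3.
#' @param x_name,y_name,group labels carried into the result.
#' @return Object of class `loglog_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `x_name`, `y_name`, `group`, and the
#'   underlying `lm` fit in `$fit`.
#' @examples
#' f <- loglog_ols(c(1, 2, 4, 8), c(1, 4, 16, 64))
#' f$slope  # 2
#' @export
loglog_ols <- function(x, y, x_name = deparse(substitute(x)),
                       y_name = deparse(substitute(y)), group = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  bad <- which(ok & (x <= 0 | y <= 0))
  if (length(bad)) {
    stop(sprintf("non-positive values cannot be log-transformed (rows: %s)",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite observations", call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  # exact power laws trigger the harmless "essentially perfect fit" warning
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  p <- if (nrow(co) >= 2L) co["lx", "Pr(>|t|)"] else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)[["lx"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = s$r.squared,
    p_value = p,
    n = length(x),
    x_name = x_name, y_name = y_name, group = group,
    fit = fit
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> log10(%s) = %.3f log10(%s) %+0.3f  (R^2 %.3f, p %.3g, n %d%s)\n",
              x$y_name, x$slope, x$x_name, x$intercept, x$r_squared,
              x$p_value, x$n,
              if (is.na(x$group)) "" else paste0(", ", x$group)))
  invisible(x)
}

#' @export
as.data.frame.loglog_fit <- function(x, ...) {
  data.frame(y_name = x$y_name, x_name = x$x_name, group = x$group,
             slope = x$slope, intercept = x$intercept,
             r_squared = x$r_squared, p_value = x$p_value, n = x$n,
             stringsAsFactors = FALSE)
}

#' Test for equality of two log-log regression slopes
#'
#' Pools the two datasets with a group indicator and tests the
#' group-by-log10(x) interaction term by OLS, returning the two-sided
#' p-value for slope equality.
#'
#' @param fit1,fit2 `loglog_fit` objects.
#' @return List with `p_value`, `slope_difference` (slope2 - slope1), and
#'   the pooled `lm` fit.
#' @export
slope_difference_test <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "loglog_fit"), inherits(fit2, "loglog_fit"))
  m1 <- stats::model.frame(fit1$fit)
  m2 <- stats::model.frame(fit2$fit)
  df <- rbind(
    data.frame(ly = m1[[1]], lx = m1[[2]], g = 0),
    data.frame(ly = m2[[1]], lx = m2[[2]], g = 1)
  )
  pooled <- stats::lm(ly ~ lx * g, data = df)
  co <- summary(pooled)$coefficients
  if ("lx:g" %in% rownames(co)) {
    p <- co["lx:g", "Pr(>|t|)"]
    d <- co["lx:g", "Estimate"]
  } else {
    p <- NA_real_; d <- NA_real_
  }
  # identical datasets give an exactly zero interaction with ~zero residual;
  # report p = 1 for a zero estimated difference
  if (is.finite(d) && abs(d) < 1e-12) p <- 1
  list(p_value = p, slope_difference = d, fit = pooled)
}

#' Table-2-style regression report over a cohort table
#'
#' Fits log-log OLS of each response against a predictor, optionally within
#' groups (e.g. species) and/or pooled, after aggregating to per-individual
#' means (the default regression level).
#'
#' @param data data.frame with one row per lunge (or per individual).
#' @param responses character vector of response column names.
#' @param predictor predictor column name (e.g. `"L_body"` or `"U_MO"`).
#' @param group optional grouping column name (fits per group plus pooled).
#' @param by_individual aggregate to per-individual means first (requires an
#'   `individual_id` column); default TRUE.
#' @return data.frame with one row per (response, group) fit.
#' @export
regression_report <- function(data, responses, predictor, group = NULL,
                              by_individual = TRUE) {
  if (by_individual) {
    if (!"individual_id" %in% names(data)) {
      stop("by_individual = TRUE requires an individual_id column", call. = FALSE)
    }
    keep <- unique(c("individual_id", group, predictor, responses))
    num <- setdiff(keep, c("individual_id", group))
    agg <- stats::aggregate(data[num], by = data[c("individual_id", group)],
                            FUN = mean, na.rm = TRUE)
    data <- agg
  }
  fit_rows <- list()
  add_fit <- function(y, d, label) {
    f <- try(loglog_ols(d[[predictor]], d[[y]], x_name = predictor,
                        y_name = y, group = label), silent = TRUE)
    if (!inherits(f, "try-error")) {
      fit_rows[[length(fit_rows) + 1L]] <<- as.data.frame(f)
    }
  }
  for (y in responses) {
    add_fit(y, data, "pooled")
    if (!is.null(group)) {
      for (g in unique(data[[group]])) {
        add_fit(y, data[data[[group]] == g, , drop = FALSE], g)
      }
    }
  }
  do.call(rbind, fit_rows)
}
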