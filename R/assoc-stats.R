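#' Simple linear regression with explicit statistics
#'
#' Ordinary least squares of one response on one predictor, as used for the
#' locus length-vs-informativeness and congruence-vs-branch-duration
#' analyses.  The p-value is two-sided for the slope, from the t statistic
#' on n - 2 degrees of freedom.  A zero-variance response is a well-defined
#' degenerate case (slope 0, R-squared defined as 0, p = 1); a constant
#' predictor is an error.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the predictor and response.
#' @return An object of class `congrue_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `adj_r_squared`, `p_value`, `n`, the term
#'   names, and the scatter `data` used; supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @examples
#' d <- data.frame(len = c(1, 2, 3, 4, 5), pic = c(2, 1, 4, 3, 6))
#' linear_fit(d, len, pic)
#' @export
linear_fit <- function(data, x, y) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  xv <- as.numeric(data[[x_name]])
  yv <- as.numeric(data[[y_name]])
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(xv) == 0) {
    stop("predictor '", x_name, "' is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  co <- stats::coef(fit)
  if (stats::var(yv) == 0) {
    slope <- 0; intercept <- yv[1L]
    r2 <- 0; se <- 0; tstat <- 0; p <- 1
  } else {
    # an exactly collinear fit is legitimate here (p is clamped below)
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    slope <- unname(co[2L]); intercept <- unname(co[1L])
    r2 <- sm$r.squared
    se <- sm$coefficients[2L, 2L]
    tstat <- sm$coefficients[2L, 3L]
    p <- sm$coefficients[2L, 4L]
    p <- min(max(p, .Machine$double.xmin), 1)  # clamp underflow, keep p in (0, 1]
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(
    list(
      slope = slope, intercept = intercept,
      r_squared = r2, adj_r_squared = adj,
      std_error = se, statistic = tstat, p_value = p, n = n,
      x_name = x_name, y_name = y_name,
      data = tibble::tibble(!!x_name := xv, !!y_name := yv)
    ),
    class = "congrue_fit"
  )
}

#' @export
print.congrue_fit <- function(x, digits = 4, ...) {
  cat("Simple linear fit: ", x$y_name, " ~ ", x$x_name,
      "  (n = ", x$n, ")\n", sep = "")
  cat("  slope     = ", format(x$slope, digits = digits),
      "  (p = ", format(x$p_value, digits = digits), ")\n", sep = "")
  cat("  intercept = ", format(x$intercept, digits = digits), "\n", sep = "")
  cat("  R^2 = ", format(x$r_squared, digits = digits),
      ", adj. R^2 = ", format(x$adj_r_squared, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Congruence versus branch duration
#'
#' Regresses gene-tree support on branch duration across the bipartitions
#' of a congruence table joined to a chronogram
#' ([add_branch_durations()]).  The expected signature of a rapid radiation
#' is a positive slope: short branches leave few loci time to sort, long
#' branches accumulate concordant gene trees.
#'
#' @param joined A `tbl_congruence` with a `duration` column.
#' @param response `"n_support"` (raw count of supporting gene trees,
#'   default) or `"fraction"` (support fraction under the table's trivial
#'   policy; useful when denominators differ across datasets).
#' @return A [linear_fit()] object (`congrue_fit`).
#' @export
congruence_duration_fit <- function(joined, response = c("n_support", "fraction")) {
  response <- match.arg(response)
  if (!is.data.frame(joined) || !all(c("duration", response) %in% names(joined))) {
    stop("`joined` must be a congruence table with `duration` and `",
         response, "` columns (see add_branch_durations())", call. = FALSE)
  }
  usable <- joined[is.finite(joined$duration), , drop = FALSE]
  dropped <- nrow(joined) - nrow(usable)
  if (dropped > 0L) {
    message(dropped, " row(s) without a branch duration excluded from the fit")
  }
  if (nrow(usable) < 3L) {
    stop("fewer than 3 bipartitions with branch durations; cannot fit",
         call. = FALSE)
  }
  linear_fit(usable, duration, !!rlang::sym(response))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy congrue_fit
#' @export
tidy.congrue_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$x_name),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$std_error),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @method glance congrue_fit
#' @export
glance.congrue_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    p.value = x$p_value,
    nobs = x$n
  )
}
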