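#' Estimate burrow use efficiency from thermoregulation-axes points
#'
#' OLS of the thermoregulation capacity y = Tb - S on the cooling capacity
#' x = B - S. The slope is the burrow use efficiency E_B (0 = burrow ignored,
#' 1 = body tracks the burrow completely) and the intercept is the no-refuge
#' offset b = Te^hat - S, the amount by which a crab runs warmer than the
#' surface when the burrow offers no thermal refuge (B = S), set by the
#' body's passive thermal properties.
#'
#' @param points data.frame with columns `cooling_capacity_c` and
#'   `thermoreg_capacity_c` (see [compute_axes()]), or a list/data.frame with
#'   columns `x` and `y`.
#' @return A `linear_fit` (see [fit_ols()]) with extra elements `e_b`
#'   (= slope) and `b_offset` (= intercept) and subclass `eb_fit`.
#' @export
estimate_eb <- function(points) {
  if (all(c("cooling_capacity_c", "thermoreg_capacity_c") %in% names(points))) {
    x <- points$cooling_capacity_c
    y <- points$thermoreg_capacity_c
  } else if (all(c("x", "y") %in% names(points))) {
    x <- points$x; y <- points$y
  } else {
    stop("points must carry cooling/thermoregulation capacities (x, y)")
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || stats::var(x[ok]) == 0) {
    stop("burrow temperatures did not vary enough to identify the burrow ",
         "use efficiency (need >= 3 points with non-constant cooling capacity)")
  }
  fit <- fit_ols(x[ok], y[ok])
  fit$e_b <- fit$slope
  fit$b_offset <- fit$intercept
  class(fit) <- c("eb_fit", class(fit))
  fit
}

#' @export
print.eb_fit <- function(x, digits = 3, ...) {
  cat("Thermoregulation-axes fit (y = Tb - S on x = B - S), n =", x$n, "\n")
  cat(sprintf("  burrow use efficiency E_B = %.*f (SE %.*f)\n",
              digits, x$e_b, digits, x$slope_se))
  cat(sprintf("  no-refuge offset b = Te^hat - S = %.*f degC (SE %.*f)\n",
              digits, x$b_offset, digits, x$intercept_se))
  cat(sprintf("  R-squared %.*f\n", digits, x$r_squared))
  invisible(x)
}

#' Estimate the thermoregulation onset temperature
#'
#' Given the regression of thermoregulation capacity on surface temperature,
#' Tb - S = m*S + c (slope m must be negative: the capacity declines as the
#' surface warms), and the no-refuge offset b from the thermoregulation axes,
#' the onset is found where the fitted line meets the no-thermoregulation
#' level b: the surface temperature at onset is S* = (b - c)/m, and the body
#' temperature at onset is T_reg = S* + b. The x-intercept of the line,
#' -c/m, is an upper bound for T_reg (it is where the crab body would match
#' the surface exactly, which with b > 0 happens at a warmer surface than the
#' onset).
#'
#' When the slope is non-negative the onset is undefined (the fitted capacity
#' never declines to the no-refuge level); a reason-coded absence is returned
#' rather than a number.
#'
#' Standard errors for T_reg are propagated by the delta method on (m, c, b),
#' using the within-fit slope/intercept covariance of the surface regression
#' and treating the two regressions as independent. The source study reports
#' no uncertainty for the onset; the SE is this package's extension.
#'
#' @param fit_tbs_vs_s A `linear_fit` of Tb - S on S (see [fit_ols()]).
#' @param b_offset The no-refuge offset b (degrees C), or an `eb_fit` from
#'   [estimate_eb()] (its intercept and SE are used).
#' @return Object of class `treg_estimate`: `surface_at_onset`, `t_reg`,
#'   `t_reg_upper`, `t_reg_se` (NA when b's uncertainty is unknown), `m`,
#'   `c`, `b_offset`, and `reason` (NULL when defined, otherwise a code such
#'   as `"nonnegative_slope"` with all estimates NA).
#' @export
estimate_treg <- function(fit_tbs_vs_s, b_offset) {
  stopifnot(inherits(fit_tbs_vs_s, "linear_fit"))
  b_se <- NA_real_
  if (inherits(b_offset, "linear_fit")) {
    b_se <- b_offset$intercept_se
    b_offset <- b_offset$intercept
  }
  stopifnot(is.numeric(b_offset), length(b_offset) == 1, is.finite(b_offset))
  m <- fit_tbs_vs_s$slope
  c_ <- fit_tbs_vs_s$intercept
  if (m >= 0) {
    return(structure(list(
      surface_at_onset = NA_real_, t_reg = NA_real_, t_reg_upper = NA_real_,
      t_reg_se = NA_real_, m = m, c = c_, b_offset = b_offset,
      reason = "nonnegative_slope"
    ), class = "treg_estimate"))
  }
  s_star <- (b_offset - c_) / m
  t_reg <- s_star + b_offset
  t_reg_upper <- -c_ / m

  # delta method: T_reg = (b - c)/m + b
  # dT/dm = -(b - c)/m^2, dT/dc = -1/m, dT/db = 1/m + 1
  var_m <- fit_tbs_vs_s$slope_se^2
  var_c <- fit_tbs_vs_s$intercept_se^2
  cov_mc <- fit_tbs_vs_s$cov_slope_intercept %||% 0
  dm <- -(b_offset - c_) / m^2
  dc <- -1 / m
  db <- 1 / m + 1
  var_t <- dm^2 * var_m + dc^2 * var_c + 2 * dm * dc * cov_mc
  if (!is.na(b_se)) var_t <- var_t + db^2 * b_se^2
  structure(list(
    surface_at_onset = s_star, t_reg = t_reg, t_reg_upper = t_reg_upper,
    t_reg_se = sqrt(var_t), m = m, c = c_, b_offset = b_offset,
    reason = NULL
  ), class = "treg_estimate")
}

#' @export
print.treg_estimate <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Thermoregulation onset: undefined (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Thermoregulation onset T_reg = %.2f degC", x$t_reg))
  if (is.finite(x$t_reg_se)) cat(sprintf(" (delta-method SE %.2f)", x$t_reg_se))
  cat("\n")
  cat(sprintf("  surface temperature at onset S* = %.2f degC\n",
              x$surface_at_onset))
  cat(sprintf("  upper bound (x-intercept)       = %.2f degC\n", x$t_reg_upper))
  invisible(x)
}

#' Marginal body-temperature response to surface warming
#'
#' The regression of thermoregulation capacity on surface temperature,
#' Tb - S = m*S + c, implies d(Tb)/dS = 1 + m: a slope of -0.30 means the
#' body warms 0.70 degrees C for each 1 degree C of surface warming.
#'
#' @param fit_tbs_vs_s A `linear_fit` of Tb - S on S, or a bare numeric slope.
#' @return Numeric, degrees C of body warming per degree C of surface warming.
#' @export
implied_tb_sensitivity <- function(fit_tbs_vs_s) {
  m <- if (inherits(fit_tbs_vs_s, "linear_fit")) fit_tbs_vs_s$slope
       else as.numeric(fit_tbs_vs_s)
  stopifnot(length(m) == 1, is.finite(m))
  1 + m
}

#' Contrast thermoregulation estimates between two groups
#'
#' Differences (a - b) in burrow use efficiency, no-refuge offset, and onset
#' temperature between two groups, with standard errors propagated assuming
#' the two groups' fits are independent (delta method).
#'
#' @param estimates_a,estimates_b Lists with elements `eb_fit` (an
#'   [estimate_eb()] result) and `treg` (an [estimate_treg()] result), as
#'   produced per group by [run_pipeline()]; or bare `eb_fit` objects.
#' @return Object of class `thermoreg_contrast`: data.frame with one row per
#'   quantity (`e_b`, `b_offset`, `t_reg`), columns `difference` and `se`.
#' @export
group_contrast <- function(estimates_a, estimates_b) {
  wrap <- function(e) {
    if (inherits(e, "eb_fit")) list(eb_fit = e, treg = NULL) else e
  }
  a <- wrap(estimates_a); b <- wrap(estimates_b)
  stopifnot(inherits(a$eb_fit, "eb_fit"), inherits(b$eb_fit, "eb_fit"))
  rows <- data.frame(
    quantity = c("e_b", "b_offset"),
    difference = c(a$eb_fit$e_b - b$eb_fit$e_b,
                   a$eb_fit$b_offset - b$eb_fit$b_offset),
    se = c(sqrt(a$eb_fit$slope_se^2 + b$eb_fit$slope_se^2),
           sqrt(a$eb_fit$intercept_se^2 + b$eb_fit$intercept_se^2)),
    stringsAsFactors = FALSE
  )
  if (!is.null(a$treg) && !is.null(b$treg) &&
      is.null(a$treg$reason) && is.null(b$treg$reason)) {
    rows <- rbind(rows, data.frame(
      quantity = "t_reg",
      difference = a$treg$t_reg - b$treg$t_reg,
      se = sqrt(a$treg$t_reg_se^2 + b$treg$t_reg_se^2),
      stringsAsFactors = FALSE
    ))
  }
  structure(list(contrasts = rows), class = "thermoreg_contrast")
}

#' @export
print.thermoreg_contrast <- function(x, ...) {
  cat("Group contrasts (a - b):\n")
  tab <- x$contrasts
  tab$difference <- round(tab$difference, 3)
  tab$se <- round(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
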