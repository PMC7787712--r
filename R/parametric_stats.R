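#' Ordinary least squares fit of y on x
#'
#' Simple linear regression solved directly from the normal equations:
#' slope = Sxy / Sxx, intercept = ybar - slope * xbar. Returns the quantities
#' the thermoregulation estimators need: coefficient standard errors from the
#' residual variance SSE / (n - 2), the slope/intercept covariance
#' (-xbar * sigma^2 / Sxx, needed for delta-method error propagation), and
#' R-squared.
#'
#' @param x Numeric predictor vector (degrees C in this package's analyses).
#' @param y Numeric response vector, same length as `x`.
#' @return Object of class `linear_fit`: slope, intercept, r_squared, n,
#'   slope_se, intercept_se, cov_slope_intercept, sigma2, residuals, fitted,
#'   and the input means.
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete observations are required")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate design: x is constant, slope is undefined")
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  resid <- y - fitted
  sse <- sum(resid^2)
  syy <- sum((y - ybar)^2)
  r2 <- if (syy == 0) 0 else 1 - sse / syy
  sigma2 <- sse / (n - 2)
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    n = n,
    slope_se = sqrt(sigma2 / sxx),
    intercept_se = sqrt(sigma2 * (1 / n + xbar^2 / sxx)),
    cov_slope_intercept = -xbar * sigma2 / sxx,
    sigma2 = sigma2,
    residuals = resid,
    fitted = fitted,
    x_mean = xbar,
    y_mean = ybar
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat("Linear fit (OLS), n =", x$n, "\n")
  cat(sprintf("  slope     %8.*f  (SE %.*f)\n", digits, x$slope, digits,
              x$slope_se))
  cat(sprintf("  intercept %8.*f  (SE %.*f)\n", digits, x$intercept, digits,
              x$intercept_se))
  cat(sprintf("  R-squared %8.*f\n", digits, x$r_squared))
  invisible(x)
}

# least-squares residual SS and rank for an arbitrary design matrix
ls_sse <- function(X, y) {
  qrx <- qr(X)
  res <- qr.resid(qrx, y)
  list(sse = sum(res^2), rank = qrx$rank)
}

#' Analysis of covariance with sequential (Type-I) sums of squares
#'
#' Fits the nested sequence covariate-only, + size, + size:covariate
#' interaction, and tests each added term with an F-ratio against the
#' residual mean square of the fullest model. `size` may be a two-level
#' factor (the sex-by-size class convention) or a continuous variable
#' (carapace width); the covariate is typically surface temperature or the
#' burrow cooling capacity. The interaction F is the homogeneity-of-slopes
#' test.
#'
#' The `offset_sqrt` transform shifts the response to positivity and takes
#' square roots, sqrt(y - min(y) + 0.01); it exists to replicate
#' normality-restoring hypothesis tests and must not be used when coefficient
#' estimates on the degrees-Celsius scale are needed.
#'
#' @param y Numeric response (thermoregulation capacity, degrees C).
#' @param size Factor/character with >= 1 level, or numeric (continuous size).
#' @param covariate Numeric covariate.
#' @param include_interaction Test the size x covariate interaction? Default
#'   TRUE.
#' @param transform "none" (default) or "offset_sqrt".
#' @return Object of class `ancova_result`: an ANOVA `table` (term, df, ss,
#'   ms, f, p), convenience fields `f_covariate`/`p_covariate`,
#'   `f_factor`/`p_factor`, `f_interaction`/`p_interaction`, df pairs,
#'   `transform_applied`, `size_type`, and `group_fits` (per-level
#'   [fit_ols()] fits when size is categorical).
#' @export
ancova <- function(y, size, covariate, include_interaction = TRUE,
                   transform = c("none", "offset_sqrt")) {
  transform <- match.arg(transform)
  y <- as.numeric(y)
  covariate <- as.numeric(covariate)
  n <- length(y)
  if (length(covariate) != n || length(size) != n) {
    stop("y, size, and covariate must have equal length")
  }
  ok <- !is.na(y) & !is.na(covariate) & !is.na(size)
  y <- y[ok]; covariate <- covariate[ok]; size <- size[ok]
  n <- length(y)
  if (n < 4) stop("too few complete observations for an ANCOVA")

  size_numeric <- is.numeric(size)
  if (size_numeric) {
    size_term <- size
    levels_ <- NULL
  } else {
    size <- factor(size)
    levels_ <- levels(size)
    tab <- table(size)
    if (any(tab < 2)) {
      stop("each size level needs at least 2 observations (empty or ",
           "singleton level: ", paste(names(tab)[tab < 2], collapse = ", "),
           ")")
    }
    for (lv in levels_) {
      if (stats::var(covariate[size == lv]) == 0) {
        stop("covariate is constant within level '", lv, "'")
      }
    }
    size_term <- as.numeric(size == levels_[min(2L, length(levels_))])
    if (length(levels_) > 2) stop("size must have at most 2 levels")
  }
  if (stats::var(covariate) == 0) stop("covariate is constant")

  if (transform == "offset_sqrt") y <- sqrt(y - min(y) + 0.01)

  one <- rep(1, n)
  X0 <- cbind(one)
  X1 <- cbind(one, covariate)
  single_level <- !size_numeric && length(levels_) == 1
  designs <- list(X1)
  term_names <- "covariate"
  if (!single_level) {
    X2 <- cbind(X1, size_term)
    designs <- c(designs, list(X2))
    term_names <- c(term_names, "size")
    if (include_interaction) {
      X3 <- cbind(X2, size_term * covariate)
      designs <- c(designs, list(X3))
      term_names <- c(term_names, "size:covariate")
    }
  }

  sse0 <- ls_sse(X0, y)
  fits <- lapply(designs, ls_sse, y = y)
  full <- fits[[length(fits)]]
  df_res <- n - full$rank
  if (df_res < 1) stop("no residual degrees of freedom")
  ms_res <- full$sse / df_res
  # a model that explains the response to machine precision is saturated
  sat_tol <- 1e-10 * max(sse0$sse, 1)
  saturated <- full$sse <= sat_tol

  prev_sse <- sse0$sse; prev_rank <- sse0$rank
  rows <- list()
  for (i in seq_along(fits)) {
    ss <- prev_sse - fits[[i]]$sse
    df <- fits[[i]]$rank - prev_rank
    # saturated (zero-residual) designs: a term with zero incremental SS has
    # F = 0, one with positive SS is infinitely significant
    f <- if (df <= 0) NA_real_
         else if (!saturated) (ss / df) / ms_res
         else if (ss <= sat_tol) 0 else Inf
    p <- if (df > 0) stats::pf(f, df, df_res, lower.tail = FALSE) else NA_real_
    rows[[i]] <- data.frame(term = term_names[i], df = df, ss = ss,
                            ms = if (df > 0) ss / df else NA_real_,
                            f = f, p = p, stringsAsFactors = FALSE)
    prev_sse <- fits[[i]]$sse; prev_rank <- fits[[i]]$rank
  }
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(term = "residual", df = df_res, ss = full$sse,
                               ms = ms_res, f = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE))

  pick <- function(term, col) {
    v <- tab[[col]][tab$term == term]
    if (length(v)) v else NA_real_
  }
  group_fits <- NULL
  if (!size_numeric && transform == "none") {
    group_fits <- lapply(stats::setNames(levels_, levels_), function(lv) {
      fit_ols(covariate[size == lv], y[size == lv])
    })
  }
  structure(list(
    table = tab,
    f_covariate = pick("covariate", "f"),
    p_covariate = pick("covariate", "p"),
    df_covariate = c(pick("covariate", "df"), df_res),
    f_factor = pick("size", "f"),
    p_factor = pick("size", "p"),
    df_factor = c(pick("size", "df"), df_res),
    f_interaction = pick("size:covariate", "f"),
    p_interaction = pick("size:covariate", "p"),
    df_interaction = c(pick("size:covariate", "df"), df_res),
    n = n,
    transform_applied = transform,
    size_type = if (size_numeric) "continuous" else "class",
    group_fits = group_fits
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("ANCOVA (sequential SS), n =", x$n,
      if (x$transform_applied != "none") {
        paste0("[response transform: ", x$transform_applied, "]")
      } else "", "\n")
  tab <- x$table
  tab$ss <- round(tab$ss, 4); tab$ms <- round(tab$ms, 4)
  tab$f <- round(tab$f, 3); tab$p <- round(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
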