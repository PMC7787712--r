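# run code with a private, restored RNG state so analyses are reproducible
# without disturbing the caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("supply a list of numeric vectors")
  if (!is.list(groups)) stop("supply a list of numeric vectors")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) == 0)) stop("every group must be non-empty")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

# tie-correction denominator 1 - sum(t^3 - t) / (N^3 - N)
tie_correction <- function(pooled) {
  t <- table(pooled)
  n <- length(pooled)
  1 - sum(t^3 - t) / (n^3 - n)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of k group location distributions. Pooled average
#' ranks are used for ties and the statistic is divided by the standard tie
#' correction 1 - sum(t^3 - t)/(N^3 - N); the p-value is chi-squared on k - 1
#' degrees of freedom. Used here for the monthly comparisons of body
#' temperature across the four sex-by-size classes.
#'
#' @param groups List of numeric vectors (one per group), NAs dropped.
#' @return Object of class `kruskal_result`: `h_statistic`, `df`, `p_value`,
#'   `group_ns`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  ns <- vapply(groups, length, 1L)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), ns)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(ns * (rbar - (n + 1) / 2)^2)
  cc <- tie_correction(pooled)
  if (cc <= 0) {
    # all observations identical: no rank separation is possible
    h <- 0
  } else {
    h <- h / cc
  }
  df <- length(groups) - 1L
  structure(list(
    h_statistic = h,
    df = df,
    p_value = stats::pchisq(h, df, lower.tail = FALSE),
    group_ns = stats::setNames(as.integer(ns), names(groups))
  ), class = "kruskal_result")
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.3f, p = %.3f  (n = %s)\n",
              x$df, x$h_statistic, x$p_value,
              paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons with Bonferroni correction
#'
#' Pairwise z-statistics from pooled-rank mean differences with the
#' tie-corrected variance N(N+1)/12 - sum(t^3 - t)/(12(N-1)); two-sided
#' normal p-values, Bonferroni-adjusted over all k(k-1)/2 pairs
#' (adjusted p = min(1, raw p x number of comparisons)).
#'
#' @param groups List of numeric vectors, as for [kruskal_wallis()].
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `dunn_result`: data.frame `comparisons` with
#'   columns `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  ns <- vapply(groups, length, 1L)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), ns)
  rbar <- tapply(r, idx, mean)
  t <- table(pooled)
  var_base <- n * (n + 1) / 12 - sum(t^3 - t) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / ns[i] + 1 / ns[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               z = z, p_raw = p, p_adjusted = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)
  comparisons$significant <- comparisons$p_adjusted < alpha
  rownames(comparisons) <- NULL
  structure(list(comparisons = comparisons, alpha = alpha,
                 n_comparisons = m), class = "dunn_result")
}

#' @export
print.dunn_result <- function(x, ...) {
  cat(sprintf("Dunn's pairwise comparisons (Bonferroni over %d pairs, alpha = %g)\n",
              x$n_comparisons, x$alpha))
  tab <- x$comparisons
  tab$z <- round(tab$z, 3); tab$p_raw <- round(tab$p_raw, 4)
  tab$p_adjusted <- round(tab$p_adjusted, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Gower-centered matrix G = -0.5 * C A C with A the squared Euclidean
# distances; tr(H G) for a hat matrix H gives the model sum of squares of
# the distance-based linear model (McArdle-Anderson partitioning)
gower_center <- function(response) {
  y <- as.matrix(response)
  d2 <- as.matrix(stats::dist(y, method = "euclidean"))^2
  if (all(d2 == 0)) stop("degenerate distance matrix: all interpoint distances are zero")
  n <- nrow(d2)
  a <- -0.5 * d2
  rm_ <- rowMeans(a); gm <- mean(a)
  a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

#' Permutational ANOVA on a Euclidean distance matrix (pseudo-F)
#'
#' Distance-based linear model with sequential partitioning of the total sum
#' of squared interpoint distances: each model term in `terms` is added in
#' order, its sum of squares is the increase in tr(H G) (H the hat matrix of
#' the design so far, G the Gower-centered matrix of -0.5 x squared
#' distances), and its pseudo-F is the term mean square over the residual
#' mean square of the full model. Significance is assessed by free
#' permutation of the rows of the response; the permutation p-value is
#' (number of permuted pseudo-F >= observed + 1) / (n_perm + 1), so its floor
#' is 1/(n_perm + 1).
#'
#' For a univariate response with Euclidean distance this reproduces the
#' classical ANOVA/ANCOVA sequential F-ratios exactly (algebraic identity).
#'
#' @param response Numeric vector or matrix (rows = observations).
#' @param terms Named list of model terms, in entry order. Each element is a
#'   numeric vector or a factor/character vector of the same length as the
#'   response rows; an element named like `"a:b"` may be given directly as the
#'   product of a dummy and a covariate, or construct it yourself.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed driving the permutation stream (required).
#' @return Object of class `permanova_result`: data.frame `table` (term, df,
#'   ss, ms, pseudo_f, p_perm) with residual and total rows, plus `n_perm`
#'   and `seed`.
#' @export
permanova <- function(response, terms, n_perm = 999, seed) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  if (n_perm < 99) stop("use at least 99 permutations")
  y <- as.matrix(response)
  n <- nrow(y)
  if (n < 5) stop("at least 5 observations are required")
  if (!is.list(terms) || is.null(names(terms)) || any(names(terms) == "")) {
    stop("terms must be a named list, in the order they enter the model")
  }
  cols <- lapply(terms, function(v) {
    if (length(v) != n && !is.matrix(v)) stop("term length does not match response")
    if (is.numeric(v)) {
      matrix(as.numeric(v), nrow = n)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) stop("categorical term has fewer than 2 levels")
      stats::model.matrix(~ f)[, -1, drop = FALSE]
    }
  })

  g <- gower_center(y)
  ss_total <- sum(diag(g))

  # hat-matrix model SS via the thin Q of each nested design
  one <- matrix(1, n, 1)
  x <- one
  qlist <- list()
  ranks <- integer(length(cols))
  prev_rank <- 1L
  for (i in seq_along(cols)) {
    x <- cbind(x, cols[[i]])
    qrx <- qr(x)
    qlist[[i]] <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    ranks[i] <- qrx$rank
    if (ranks[i] <= prev_rank) {
      stop("term '", names(terms)[i], "' adds no estimable effect (aliased)")
    }
    prev_rank <- ranks[i]
  }
  df_terms <- diff(c(1L, ranks))
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")

  # tr(Q Q' G) = sum(Q * (G Q)); model SS for an intercept-only fit is 0
  # because G is doubly centered
  model_ss <- function(gmat) {
    vapply(qlist, function(q) sum(q * (gmat %*% q)), 1.0)
  }
  stats_for <- function(gmat) {
    cum <- model_ss(gmat)
    ss <- diff(c(0, cum))
    ss_res <- sum(diag(gmat)) - cum[length(cum)]
    (ss / df_terms) / (ss_res / df_res)
  }

  f_obs <- stats_for(g)
  exceed <- rep(0L, length(f_obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fp <- stats_for(g[p, p, drop = FALSE])
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
  })
  p_perm <- (exceed + 1) / (n_perm + 1)

  cum <- model_ss(g)
  ss <- diff(c(0, cum))
  ss_res <- ss_total - cum[length(cum)]
  tab <- data.frame(
    term = c(names(terms), "residual", "total"),
    df = c(df_terms, df_res, n - 1L),
    ss = c(ss, ss_res, ss_total),
    ms = c(ss / df_terms, ss_res / df_res, NA_real_),
    pseudo_f = c(f_obs, NA_real_, NA_real_),
    p_perm = c(p_perm, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean, sequential SS, %d permutations, seed %d)\n",
              x$n_perm, x$seed))
  tab <- x$table
  tab$ss <- round(tab$ss, 4); tab$ms <- round(tab$ms, 4)
  tab$pseudo_f <- round(tab$pseudo_f, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
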