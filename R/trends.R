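# Outlier screening, summaries, and concentration-trend regressions.

#' Two-sided Grubbs critical value
#'
#' `G_crit(n, alpha) = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the
#' upper `alpha/(2n)` quantile of the t-distribution on `n-2` df.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return critical value of the maximum studentized deviation.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier filter
#'
#' Repeatedly removes the single most extreme value while
#' `G = max |x_i - mean| / sd` exceeds the two-sided critical value at the
#' current sample size. Zero-variance samples are left untouched (G is
#' undefined). Removal is capped at 20% of the group (at least one value may
#' always be tested) to avoid pathological stripping.
#'
#' @param values numeric vector (n >= 3, finite).
#' @param alpha significance level (default 0.05).
#' @param max_remove_frac cap on the fraction removed.
#' @return list of class `grubbs_result`: `kept`, `removed`, `G_statistics`
#'   (one per removal iteration, including the final non-significant G),
#'   `alpha`.
#' @export
grubbs_filter <- function(values, alpha = 0.05, max_remove_frac = 0.2) {
  if (length(values) < 3) abort_cq("Grubbs test needs n >= 3", "cq_small_n")
  if (any(!is.finite(values))) abort_cq("values must be finite", "cq_bad_values")
  kept <- values
  removed <- numeric(0)
  gs <- numeric(0)
  max_remove <- max(1L, floor(max_remove_frac * length(values)))
  repeat {
    s <- sd(kept)
    if (s == 0 || length(kept) < 3) break
    dev <- abs(kept - mean(kept))
    i <- which.max(dev)
    g <- dev[i] / s
    gs <- c(gs, g)
    if (g > grubbs_critical(length(kept), alpha) &&
        length(removed) < max_remove) {
      removed <- c(removed, kept[i])
      kept <- kept[-i]
    } else break
  }
  structure(list(kept = kept, removed = removed, G_statistics = gs,
                 alpha = alpha), class = "grubbs_result")
}

#' Simple linear regression on per-level means
#'
#' Ordinary least squares of the mean response at each distinct
#' concentration against concentration — the convention for reporting a
#' single slope per series.
#'
#' @param x concentrations.
#' @param y responses (averaged per distinct `x` before fitting).
#' @return list: `slope`, `intercept`, `r_squared`, `n` (number of level
#'   means). A constant response gives slope 0 and `r_squared` 0.
#' @export
simple_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2)
    abort_cq("need >= 2 distinct concentrations", "cq_bad_design")
  m <- aggregate(list(y = y), list(x = x), mean)
  fit <- lm(y ~ x, data = m)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((m$y - mean(m$y))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(m))
}

#' Multiple linear regression on fibrinogen and activator concentration
#'
#' Fits `y = beta0 + beta_fib * [Fg] + beta_act * [Act]` by least squares.
#' Replicate rows are averaged to per-condition means before fitting
#' (`aggregate = TRUE`, the default reporting convention here). A
#' rank-deficient design (e.g. activator held constant) is an error
#' directing the caller to [simple_regression()].
#'
#' @param data data.frame with columns `fibrinogen`, `activator` and the
#'   response.
#' @param response response column name.
#' @param aggregate average replicates per (fibrinogen, activator) cell
#'   first.
#' @return list of class `regression_model`: `response`, `beta0`,
#'   `beta_fib`, `beta_act`, `r_squared`, `n`, `full_rank`.
#' @export
multiple_regression <- function(data, response, aggregate = TRUE) {
  d <- data.frame(fibrinogen = data$fibrinogen, activator = data$activator,
                  y = data[[response]])
  d <- d[complete.cases(d), , drop = FALSE]
  if (aggregate)
    d <- aggregate(list(y = d$y),
                   list(fibrinogen = d$fibrinogen, activator = d$activator),
                   mean)
  if (nrow(d) < 3) abort_cq("need >= 3 condition rows", "cq_bad_design")
  X <- cbind(1, d$fibrinogen, d$activator)
  if (qr(X)$rank < 3)
    abort_cq(paste("rank-deficient design (a concentration is constant or",
                   "collinear): fit simple_regression on the varying axis"),
             "cq_rank_deficient")
  fit <- lm(y ~ fibrinogen + activator, data = d)
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  structure(list(response = response, beta0 = unname(coef(fit)[1]),
                 beta_fib = unname(coef(fit)[2]),
                 beta_act = unname(coef(fit)[3]),
                 r_squared = r2, n = nrow(d), full_rank = TRUE),
            class = "regression_model")
}

#' Sign-trend table across fitted models
#'
#' Tabulates the sign of each fitted coefficient per response and sample
#' type, and flags responses where the purified and plasma signs disagree
#' (e.g. lag time versus fibrinogen).
#'
#' @param models data.frame with columns `response`, `sample_type`,
#'   `beta_fib`, `beta_act`.
#' @param tol coefficients with |beta| <= tol are neutral (`"0"`).
#' @return data.frame with sign columns (`"+"`, `"-"`, `"0"`) and a
#'   `types_disagree` flag per response.
#' @export
sign_trend_table <- function(models, tol = 0) {
  sgn <- function(b) ifelse(abs(b) <= tol, "0", ifelse(b > 0, "+", "-"))
  out <- data.frame(response = models$response,
                    sample_type = models$sample_type,
                    sign_fib = sgn(models$beta_fib),
                    sign_act = sgn(models$beta_act),
                    stringsAsFactors = FALSE)
  dis <- vapply(split(out, out$response), function(d)
    length(unique(d$sign_fib)) > 1 || length(unique(d$sign_act)) > 1,
    logical(1))
  out$types_disagree <- dis[out$response]
  out
}

#' Location/spread summary of one parameter
#'
#' Both conventional summaries are computed; the caller chooses which is
#' reported via the normality flag (distribution testing itself is outside
#' this package). IQR quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector (n >= 1).
#' @param normal if `TRUE`, report mean +/- standard error of the mean;
#'   otherwise median with the interquartile range.
#' @return list: `center`, `spread` (SEM, or `c(q25, q75)`), `type`, `n`.
#' @export
summarize_values <- function(values, normal = TRUE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) abort_cq("no finite values to summarize", "cq_bad_values")
  if (normal) {
    sem <- if (n == 1) 0 else sd(values) / sqrt(n)
    list(center = mean(values), spread = sem, type = "mean_sem", n = n)
  } else {
    q <- unname(quantile(values, c(0.25, 0.75), type = 7))
    list(center = median(values), spread = q, type = "median_iqr", n = n)
  }
}
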