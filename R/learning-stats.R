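# Behavioral statistics: nonlinear least-squares fitting of the
# two-parameter logarithmic learning model Y = a ln(x) + b by
# Levenberg-Marquardt (optionally robust via iteratively reweighted
# bisquare), Jacobian-based confidence intervals, paired comparisons,
# Cohen's d and Spearman rank correlation.

# one Levenberg-Marquardt weighted least-squares solve for y ~ a ln(x) + b.
# Damping lambda starts at 1e-3, x10 on a failed step, /10 on success;
# convergence when the relative SSE change or the parameter step falls
# below 1e-10.
lm_fit_log <- function(x, y, w, max_iter = 200) {
  lx <- log(x)
  # initialization: intercept from the smallest-x observations (ln(x)~0),
  # slope from the observed range over the ln(x) span
  b0 <- mean(y[x == min(x)])
  span <- log(max(x)) - log(min(x))
  a0 <- if (span > 0) (max(y) - min(y)) / span else 0
  theta <- c(a = a0, b = b0)
  resid_at <- function(th) y - th[1] * lx - th[2]
  sse_at <- function(r) sum(w * r^2)
  r <- resid_at(theta)
  sse <- sse_at(r)
  lambda <- 1e-3
  J <- cbind(lx, 1)  # d(model)/d(a, b); residual Jacobian is -J
  JtW <- t(J * w)
  JtWJ <- JtW %*% J
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- JtW %*% r
    A <- JtWJ + lambda * diag(diag(JtWJ), 2)
    delta <- tryCatch(drop(solve(A, g)), error = function(e) NULL)
    if (is.null(delta)) {
      lambda <- lambda * 10
      next
    }
    cand <- theta + delta
    r_new <- resid_at(cand)
    sse_new <- sse_at(r_new)
    if (sse_new <= sse) {
      rel <- (sse - sse_new) / max(sse, .Machine$double.eps)
      theta <- cand; r <- r_new; sse <- sse_new
      lambda <- lambda / 10
      if (rel < 1e-10 || sqrt(sum(delta^2)) < 1e-10) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  list(theta = theta, resid = r, sse = sse, converged = converged,
       n_iter = iter, JtWJ = JtWJ)
}

#' Fit the two-parameter logarithmic learning model
#'
#' Fits `Y = a ln(x) + b` by nonlinear least squares using
#' Levenberg-Marquardt iteration. With `robust = TRUE` the fit is
#' iteratively reweighted with Tukey bisquare weights (tuning constant
#' 4.685, scale from the median absolute residual), down-weighting gross
#' outliers. 95% confidence intervals come from the Jacobian-based
#' covariance with a t quantile at `n - 2` degrees of freedom, and
#' `rmse = sqrt(SSE / (n - 2))`.
#'
#' @param x Day indices (all >= 1, at least 3 distinct values).
#' @param y Scores, same length as `x`.
#' @param robust Use iteratively reweighted bisquare weights
#'   (default `FALSE`).
#' @param conf Confidence level for the intervals (default 0.95).
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 200).
#' @return An object of class `learning_curve_fit`: `a_hat`, `b_hat`,
#'   `se_a`, `se_b`, `ci_a`, `ci_b`, `rmse`, `residuals`, `weights`,
#'   `converged`, `n_iter`, `n`.
#' @examples
#' d <- generate_behavior_dataset(a = 10, b = 90, noise_sd = 0)
#' fit_log_curve(d$data$day, d$data$score)
#' @export
fit_log_curve <- function(x, y, robust = FALSE, conf = 0.95,
                          max_iter = 200) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 3) {
    stop(structure(
      class = c("hwnav_insufficient_data", "error", "condition"),
      list(message = "need at least 3 distinct x values", call = NULL)))
  }
  if (any(x < 1)) stop("day indices must be >= 1", call. = FALSE)
  w <- rep(1, n)
  fit <- lm_fit_log(x, y, w, max_iter)
  if (robust) {
    for (k in 1:50) {
      r <- fit$resid
      s <- stats::median(abs(r)) / 0.6745
      if (s < 1e-12) break
      u <- r / (4.685 * s)
      w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w_new) < 1e-8) break
      if (max(abs(w_new - w)) < 1e-8) break
      w <- w_new
      fit <- lm_fit_log(x, y, w, max_iter)
    }
  }
  df <- n - 2L
  sigma2 <- fit$sse / df
  cov <- tryCatch(sigma2 * solve(fit$JtWJ), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se <- sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  structure(
    list(a_hat = unname(fit$theta[1]), b_hat = unname(fit$theta[2]),
         se_a = se[1], se_b = se[2],
         ci_a = unname(fit$theta[1]) + c(-1, 1) * tq * se[1],
         ci_b = unname(fit$theta[2]) + c(-1, 1) * tq * se[2],
         rmse = sqrt(sigma2),
         residuals = fit$resid,
         weights = w,
         converged = fit$converged,
         n_iter = fit$n_iter,
         n = n, robust = robust, conf = conf),
    class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf("<learning_curve_fit>%s Y = a ln(x) + b, n = %d\n",
              if (x$robust) " robust (bisquare)" else "", x$n))
  cat(sprintf("  a = %.4g  [%.4g, %.4g]\n", x$a_hat, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  b = %.4g  [%.4g, %.4g]\n", x$b_hat, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  RMSE = %.4g, %sconverged in %d iterations\n",
              x$rmse, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Predicted scores from a fitted learning curve
#'
#' @param object A `learning_curve_fit`.
#' @param newdata Optional numeric day indices (defaults to `1:14`).
#' @param ... Unused.
#' @return Numeric predictions `a_hat * ln(x) + b_hat`.
#' @export
predict.learning_curve_fit <- function(object, newdata = 1:14, ...) {
  object$a_hat * log(newdata) + object$b_hat
}

#' Paired pre/post comparison with effect size
#'
#' Two-sided paired Student's t test on post - pre differences, reported
#' together with Cohen's d (pooled variant by default).
#'
#' @param pre,post Per-subject scores, paired by position.
#' @param d_variant Effect-size variant passed to [cohens_d()].
#' @return An object of class `paired_comparison`: `mean_pre`, `mean_post`,
#'   `sd_pre`, `sd_post`, `t_stat`, `df`, `p_value`, `cohens_d`,
#'   `d_variant`, `degenerate` (`TRUE` when the differences have zero
#'   variance and the t test is undefined).
#' @export
paired_ttest <- function(pre, post, d_variant = c("pooled", "paired")) {
  d_variant <- match.arg(d_variant)
  if (length(pre) != length(post)) {
    stop(structure(
      class = c("hwnav_pairing_error", "error", "condition"),
      list(message = "pre and post must have equal length", call = NULL)))
  }
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  diffs <- post - pre
  zero_var <- stats::sd(diffs) < .Machine$double.eps^0.5 * max(1, mean(abs(diffs)))
  if (zero_var && all(abs(diffs) < .Machine$double.eps^0.5)) {
    # no change at all: the null is exactly true, not undefined
    degenerate <- FALSE
    t_stat <- 0; p <- 1
  } else if (zero_var) {
    # identical nonzero shift in every pair: t is undefined
    degenerate <- TRUE
    t_stat <- NA_real_; p <- NA_real_
  } else {
    degenerate <- FALSE
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(mean_pre = mean(pre), mean_post = mean(post),
         sd_pre = stats::sd(pre), sd_post = stats::sd(post),
         t_stat = t_stat, df = n - 1L, p_value = p,
         cohens_d = cohens_d(pre, post, d_variant),
         d_variant = d_variant, n = n, degenerate = degenerate),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> n = %d: %.2f -> %.2f\n",
              x$n, x$mean_pre, x$mean_post))
  if (x$degenerate) {
    cat("  degenerate: differences have zero variance\n")
  } else {
    cat(sprintf("  t(%d) = %.3f, p = %.4g, d(%s) = %.3f\n",
                x$df, x$t_stat, x$p_value, x$d_variant, x$cohens_d))
  }
  invisible(x)
}

#' Cohen's d effect size for paired pre/post data
#'
#' The `pooled` variant divides the mean change by
#' `sqrt((sd_pre^2 + sd_post^2) / 2)`; the `paired` variant divides the
#' mean difference by the standard deviation of the differences.
#'
#' @param pre,post Per-subject scores, paired by position.
#' @param variant `"pooled"` (default) or `"paired"`.
#' @return Numeric effect size (`NA` with a warning when the denominator
#'   is zero).
#' @export
cohens_d <- function(pre, post, variant = c("pooled", "paired")) {
  variant <- match.arg(variant)
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  denom <- switch(variant,
    pooled = sqrt((stats::var(pre) + stats::var(post)) / 2),
    paired = stats::sd(post - pre))
  if (!is.finite(denom) || denom < .Machine$double.eps) {
    warning("undefined effect size: zero-variance denominator",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(post) - mean(pre)) / denom
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average) ranks, with a two-sided p value from
#' the t approximation `t = rho sqrt((n-2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `rho`, `p_value`, `n`, and `degenerate` (`TRUE` when
#'   either input is constant and the correlation undefined).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Plot a fitted learning curve over the data
#'
#' Base-graphics analogue of the learning-curve figure: daily scores, the
#' fitted logarithmic curve and its pointwise confidence band.
#'
#' @param x A `learning_curve_fit`.
#' @param days,scores The data the fit was computed from.
#' @param ... Passed to [plot()].
#' @export
plot.learning_curve_fit <- function(x, days, scores, ...) {
  grid <- seq(min(days), max(days), length.out = 100)
  pred <- predict(x, grid)
  tq <- stats::qt(1 - (1 - x$conf) / 2, x$n - 2L)
  se_line <- sqrt(x$se_a^2 * log(grid)^2 + x$se_b^2)
  plot(days, scores, xlab = "day", ylab = "daily training score",
       ylim = range(c(scores, pred + tq * se_line, pred - tq * se_line)),
       ...)
  graphics::lines(grid, pred, lwd = 2)
  graphics::lines(grid, pred + tq * se_line, lty = 2)
  graphics::lines(grid, pred - tq * se_line, lty = 2)
  invisible(x)
}
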