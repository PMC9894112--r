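#' @export
print.social_glmm <- function(x, digits = 3, ...) {
  cat(sprintf("Social-aging GLMM: %s (parameterization %s)\n",
              x$spec$prediction_id, x$spec$parameterization))
  cat("Family:", x$spec$family, " Observations:", x$n_obs, "\n")
  if (length(x$spec$interaction)) {
    cat("Interaction", x$spec$interaction,
        if (x$interaction_pruned) "pruned (interval covered 0)\n"
        else "retained\n")
  }
  ct <- x$coefficients
  tab <- data.frame(estimate = round(ct$estimate, digits),
                    lower = round(ct$lower, digits),
                    upper = round(ct$upper, digits),
                    sig = ifelse(ct$significant, "*", ""))
  rownames(tab) <- ct$term
  print(tab)
  cat(sprintf("(intervals: %.0f%% Wald; * = interval excludes 0)\n",
              100 * x$ci_level))
  invisible(x)
}

#' @export
summary.social_glmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.social_glmm")
}

#' @export
print.summary.social_glmm <- function(x, ...) {
  print(x$fit)
  cat("\nVariance partition (linear-predictor scale):\n")
  vp <- x$fit$varshares
  vp$variance <- signif(vp$variance, 3)
  vp$share_pct <- round(vp$share_pct, 2)
  print(vp, row.names = FALSE)
  d <- x$fit$diagnostics
  cat("\nBackend:", d$backend, "\n")
  cat("Converged:", d$convergence, " PD Hessian:", d$pd_hessian, "\n")
  if (length(d$messages)) {
    cat("Fitting messages:\n")
    for (m in d$messages) cat("  -", m, "\n")
  }
  invisible(x)
}

#' @export
coef.social_glmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.social_glmm <- function(object, parm, level = 0.95, ...) {
  ct <- object$coefficients
  if (abs(level - object$ci_level) > 1e-8) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(ct$estimate - z * ct$se, ct$estimate + z * ct$se)
  } else {
    ci <- cbind(ct$lower, ct$upper)
  }
  rownames(ci) <- ct$term
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.social_glmm <- function(object, newdata = NULL, type = "link", ...) {
  if (is.null(newdata)) {
    stats::predict(object$fit, type = type, ...)
  } else {
    stats::predict(object$fit, newdata = newdata, type = type, ...)
  }
}

#' @export
residuals.social_glmm <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' @export
simulate.social_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::simulate(object$fit, nsim = nsim, ...)
}

#' Coefficient interval plot for a fitted social-aging GLMM
#'
#' Base-graphics dot-and-whisker plot of the fixed effects (intercept
#' excluded by default) with their interval bounds.
#'
#' @param x A `social_glmm`.
#' @param include_intercept Show the intercept row too.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.social_glmm <- function(x, include_intercept = FALSE, ...) {
  ct <- x$coefficients
  if (!include_intercept) ct <- ct[ct$term != "(Intercept)", , drop = FALSE]
  n <- nrow(ct)
  graphics::plot(ct$estimate, seq_len(n), xlim = range(ct$lower, ct$upper, 0),
                 yaxt = "n", ylab = "", pch = 16,
                 xlab = "estimate (link scale)",
                 main = paste(x$spec$prediction_id, x$spec$parameterization),
                 ...)
  graphics::segments(ct$lower, seq_len(n), ct$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = ct$term, las = 2, cex.axis = 0.7)
  invisible(x)
}
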