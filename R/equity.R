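## ---------------------------------------------------------------------------
## Slope and relative indices of inequality (SII / RII)
## ---------------------------------------------------------------------------

#' Ridit midpoints of ordered population groups
#'
#' The ridit of an ordered group is the midpoint of its interval on the
#' cumulative weighted population distribution: cumulative share below the
#' group plus half its own share.  These rank scores in `[0, 1]` are the
#' regressor for SII/RII.
#'
#' @param shares positive population shares of the ordered groups (poorest
#'   first); must sum to 1.
#' @return strictly increasing scores in `(0, 1)`.
#' @export
ridit_midpoints <- function(shares) {
  stopifnot(is.numeric(shares), length(shares) >= 1)
  if (any(shares <= 0)) stop("population shares must be positive",
                             call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-8)
    stop("population shares must sum to 1", call. = FALSE)
  cumsum(shares) - shares / 2
}

#' Slope and relative index of inequality
#'
#' Regresses the group-level indicator values on their ridit scores by
#' weighted least squares (weights = population shares, multiplied by
#' inverse variances when standard errors are supplied).  The slope index of
#' inequality (SII) is the fitted difference between the top and bottom of
#' the wealth distribution, `fitted(1) - fitted(0)`, in the units the values
#' are supplied in (conventionally percentage points); the relative index of
#' inequality (RII) is the ratio `fitted(1) / fitted(0)`.  A positive SII /
#' RII above 1 indicates a pro-rich distribution (richer groups higher); RII
#' below 1 is pro-poor.  Confidence intervals are delta-method by default; a
#' logistic-link variant predicts at ranks 0 and 1 from a quasibinomial fit.
#'
#' @param values indicator level per ordered group, poorest first
#'   (proportions as percentages for percentage-point SII).
#' @param shares population shares (default equal fifths).
#' @param se optional standard errors of `values` (same scale).
#' @param level confidence level.
#' @param link `"identity"` (default, matches the absolute-difference
#'   definition of SII) or `"logit"`.
#' @return object of class `uhc_sii` with components `sii`, `rii`, their
#'   CIs, the WLS coefficients and covariance, and the inputs.  `rii` is
#'   `NA` (flagged) when the fitted value at rank 0 is not positive.
#' @export
sii_rii <- function(values, shares = NULL, se = NULL, level = 0.95,
                    link = c("identity", "logit")) {
  link <- match.arg(link)
  k <- length(values)
  if (is.null(shares)) shares <- rep(1 / k, k)
  stopifnot(length(shares) == k, is.null(se) || length(se) == k)
  r <- ridit_midpoints(shares)
  if (length(unique(r)) < 2)
    stop("need at least 2 distinct rank scores", call. = FALSE)
  w <- shares
  if (!is.null(se)) {
    ## zero design SEs (degenerate cells at 0 or 1) are floored relative to
    ## the largest cell variance so the fit stays well conditioned
    v <- se^2
    if (max(v) > 0) {
      w <- shares / pmax(v, max(v) * 1e-4)
    } else se <- NULL
  }
  X <- cbind(1, r)
  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * values))
  b <- drop(b)
  names(b) <- c("intercept", "slope")
  if (!is.null(se)) {
    ## sandwich covariance with the supplied value variances
    meat <- crossprod(X, (w^2 * pmax(se^2, max(se^2) * 1e-4)) * X)
    V <- solve(A, t(solve(A, meat)))
  } else {
    e <- values - drop(X %*% b)
    sigma2 <- sum(w * e^2) / max(k - 2, 1)
    V <- sigma2 * solve(A)
  }
  dimnames(V) <- list(names(b), names(b))
  f0 <- b[[1]]
  f1 <- b[[1]] + b[[2]]
  sii <- f1 - f0
  z <- stats::qnorm(1 - (1 - level) / 2)
  sii_se <- sqrt(V[2, 2])
  sii_ci <- sii + c(-1, 1) * z * sii_se
  if (f0 > 0) {
    rii <- f1 / f0
    g <- c(-b[[2]] / f0^2, 1 / f0)
    rii_se <- sqrt(drop(t(g) %*% V %*% g))
    rii_ci <- rii + c(-1, 1) * z * rii_se
    rii_flag <- FALSE
  } else {
    rii <- NA_real_; rii_se <- NA_real_; rii_ci <- c(NA_real_, NA_real_)
    rii_flag <- TRUE
  }
  if (link == "logit") {
    ## quasibinomial fit on the proportion scale, predicted at ranks 0 and 1
    scale100 <- max(values, na.rm = TRUE) > 1
    pv <- if (scale100) values / 100 else values
    pv <- pmin(pmax(pv, 1e-6), 1 - 1e-6)
    fit <- stats::glm(pv ~ r, family = stats::quasibinomial(), weights = w)
    pr <- stats::predict(fit, newdata = data.frame(r = c(0, 1)),
                         type = "response")
    mult <- if (scale100) 100 else 1
    sii <- (pr[2] - pr[1]) * mult
    rii <- if (pr[1] > 0) pr[2] / pr[1] else NA_real_
    ## intervals retained from the linear fit's delta method
  }
  structure(list(sii = unname(sii), sii_se = sii_se, sii_ci = sii_ci,
                 rii = unname(rii), rii_se = rii_se, rii_ci = rii_ci,
                 rii_undefined = rii_flag, coefficients = b, vcov = V,
                 fitted_extremes = c(bottom = unname(f0), top = unname(f1)),
                 values = values, shares = shares, se = se, ridit = r,
                 level = level, link = link),
            class = "uhc_sii")
}

#' @export
print.uhc_sii <- function(x, ...) {
  cat("Slope / relative index of inequality\n")
  cat(sprintf("  SII: %.2f (%.0f%% CI %.2f to %.2f)\n", x$sii,
              100 * x$level, x$sii_ci[1], x$sii_ci[2]))
  if (x$rii_undefined) {
    cat("  RII: undefined (fitted value at rank 0 not positive)\n")
  } else {
    cat(sprintf("  RII: %.2f (%.0f%% CI %.2f to %.2f)\n", x$rii,
                100 * x$level, x$rii_ci[1], x$rii_ci[2]))
  }
  invisible(x)
}

#' @export
coef.uhc_sii <- function(object, ...) object$coefficients

#' @export
vcov.uhc_sii <- function(object, ...) object$vcov

#' @export
summary.uhc_sii <- function(object, ...) {
  print(object)
  cat("  fitted at rank 0 / 1:",
      sprintf("%.2f / %.2f", object$fitted_extremes[1],
              object$fitted_extremes[2]), "\n")
  invisible(object)
}

#' Inequality table from stratified coverage estimates
#'
#' Computes SII and RII for every (indicator, year) present in a
#' quintile-level coverage table, on the percentage scale.
#'
#' @param coverage a `uhc_coverage` table containing `level == "quintile"`
#'   rows (from [estimate_coverage()] or [financial_protection()]).
#' @param level confidence level.
#' @return data.frame with one row per indicator-year: SII and RII with CI
#'   bounds and the quintile inputs retained as attributes.
#' @export
equity_table <- function(coverage, level = 0.95) {
  q <- coverage[coverage$level == "quintile" & !coverage$missing, ]
  if (nrow(q) == 0) stop("no quintile-level estimates supplied",
                         call. = FALSE)
  out <- list()
  for (ind in unique(q$indicator)) {
    for (yr in sort(unique(q$year[q$indicator == ind]))) {
      cell <- q[q$indicator == ind & q$year == yr, ]
      cell <- cell[order(as.integer(cell$stratum)), ]
      if (nrow(cell) < 2) next
      shares <- cell$pop_share / sum(cell$pop_share)
      fit <- sii_rii(100 * cell$p, shares, se = 100 * cell$se, level = level)
      out[[length(out) + 1L]] <- data.frame(
        indicator = ind, year = yr,
        sii = fit$sii, sii_lo = fit$sii_ci[1], sii_hi = fit$sii_ci[2],
        rii = fit$rii, rii_lo = fit$rii_ci[1], rii_hi = fit$rii_ci[2],
        rii_undefined = fit$rii_undefined)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
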