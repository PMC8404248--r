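#' @keywords internal
"_PACKAGE"

## logit helpers used throughout; kept as thin wrappers so the scale is
## explicit at call sites
logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from one master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' pipeline stage gets its own deterministic sub-seed so that adding or
#' removing a stage does not shift the random streams of the others.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(as.double(seed)) * 48271 + h * 8191 + 1) %% 2147483646
  as.integer(s) + 1L
}

## quantiles used for all 95% intervals
ci_probs <- c(0.025, 0.975)

## weighted mean that tolerates zero total weight (returns NA)
wmean <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sum(w * x) / sw
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x > 1)
    stop(sprintf("'%s' must be a single value in (0, 1]", name), call. = FALSE)
}
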