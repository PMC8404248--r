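## ---------------------------------------------------------------------------
## Indicator construction and design-weighted estimation
## ---------------------------------------------------------------------------

#' Survey design descriptor
#'
#' Names the columns holding the design information: the stratification
#' variables, the first-stage sampling unit (PSU) and the sampling weight.
#' Variance estimation treats first-stage clusters as ultimate clusters
#' within strata.
#'
#' @param strata character vector of stratum column names.
#' @param psu PSU (cluster) column name.
#' @param weight weight column name.
#' @return list of class `uhc_design`.
#' @export
uhc_design <- function(strata = c("governorate", "residence"),
                       psu = "cluster", weight = "weight") {
  structure(list(strata = strata, psu = psu, weight = weight),
            class = "uhc_design")
}

#' Define a service indicator
#'
#' An indicator is a numerator predicate over a denominator predicate.  For
#' the built-in indicators the predicates read the `elig_<name>` /
#' `y_<name>` column convention; custom indicators supply functions of the
#' record table.  The numerator is always evaluated within the denominator,
#' so the subset property holds by construction.
#'
#' @param name indicator code.
#' @param denominator function(records) -> logical eligibility, or `NULL`
#'   to use column `elig_<name>`.
#' @param numerator function(records) -> logical outcome, or `NULL` to use
#'   column `y_<name> == 1`.
#' @param target coverage target in (0, 1]; default the 80% UHC service
#'   target.
#' @return list of class `uhc_indicator`.
#' @export
indicator_definition <- function(name, denominator = NULL, numerator = NULL,
                                 target = 0.80) {
  stop_if_not_scalar_prob(target, "target")
  structure(list(name = name, denominator = denominator,
                 numerator = numerator, target = target),
            class = "uhc_indicator")
}

indicator_masks <- function(records, def) {
  if (is.character(def)) def <- indicator_definition(def)
  stopifnot(inherits(def, "uhc_indicator"))
  if (is.null(def$denominator)) {
    col <- paste0("elig_", def$name)
    if (is.null(records[[col]]))
      stop("no eligibility column '", col, "' and no denominator predicate",
           call. = FALSE)
    den <- records[[col]] %in% TRUE
  } else den <- def$denominator(records) %in% TRUE
  if (is.null(def$numerator)) {
    col <- paste0("y_", def$name)
    if (is.null(records[[col]]))
      stop("no outcome column '", col, "' and no numerator predicate",
           call. = FALSE)
    num <- records[[col]] %in% 1
  } else num <- def$numerator(records) %in% TRUE
  list(name = def$name, den = den, num = num & den, target = def$target)
}

#' Flag catastrophic out-of-pocket health expenditure
#'
#' A household's OOP health payments are catastrophic when their share of
#' the chosen denominator strictly exceeds the threshold (default 10% of
#' total household consumption).  Alternative denominators: non-food
#' consumption, or capacity to pay (consumption minus a subsistence
#' allowance of one poverty line per member).
#'
#' @param hh household record table with `oop`, `consumption` and (for the
#'   variants) `food_consumption` / `hh_size`.
#' @param threshold share threshold in (0, 1]; comparison is strict.
#' @param denominator `"total"` (default), `"nonfood"`, or `"ctp"`.
#' @param poverty_line currency/person/day, needed for `"ctp"`.
#' @param days_per_period length of the consumption recall period in days.
#' @return logical vector, one flag per household.
#' @export
flag_catastrophic <- function(hh, threshold = 0.10,
                              denominator = c("total", "nonfood", "ctp"),
                              poverty_line = NULL, days_per_period = 30) {
  stop_if_not_scalar_prob(threshold, "threshold")
  denominator <- match.arg(denominator)
  if (any(bad <- !(hh$consumption > 0))) {
    ids <- if (!is.null(hh$record_id)) hh$record_id[bad] else which(bad)
    stop("non-positive total consumption for household(s): ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  den <- switch(denominator,
    total = hh$consumption,
    nonfood = hh$consumption - hh$food_consumption,
    ctp = {
      if (is.null(poverty_line))
        stop("'poverty_line' required for capacity-to-pay denominator",
             call. = FALSE)
      hh$consumption - poverty_line * hh$hh_size * days_per_period
    })
  den <- pmax(den, .Machine$double.eps)
  hh$oop / den > threshold
}

#' Flag impoverishing out-of-pocket health expenditure
#'
#' A household is impoverished by health payments when it is non-poor on
#' per-capita consumption but falls below the poverty line once OOP health
#' spending is subtracted.  Households already poor before payment are never
#' flagged.
#'
#' @param hh household record table with `consumption`, `oop`, `hh_size`.
#' @param poverty_line currency per person per day.
#' @param days_per_period consumption recall period in days.
#' @return logical vector, one flag per household.
#' @export
flag_impoverishment <- function(hh, poverty_line, days_per_period = 30) {
  stopifnot(is.numeric(poverty_line), poverty_line > 0)
  if (is.null(hh$hh_size) || any(!is.finite(hh$hh_size)) ||
      any(hh$hh_size < 1))
    stop("household size must be defined and >= 1", call. = FALSE)
  percap <- hh$consumption / (hh$hh_size * days_per_period)
  percap_net <- (hh$consumption - hh$oop) / (hh$hh_size * days_per_period)
  percap >= poverty_line & percap_net < poverty_line
}

#' Assign weighted wealth quintiles
#'
#' Ranks units by a wealth index and cuts the weighted population
#' distribution into fifths, so each quintile holds 20% of the weighted
#' population up to the one unit straddling a cut point.  Ties are broken by
#' stable record order.
#'
#' @param index numeric wealth index.
#' @param weights sampling weights (default equal).
#' @return integer quintile labels 1 (poorest) to 5 (richest).
#' @export
assign_wealth_quintiles <- function(index, weights = NULL) {
  n <- length(index)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0), all(is.finite(index)))
  if (length(unique(index)) == 1L)
    stop("wealth index is constant; quintiles undefined", call. = FALSE)
  r <- weighted_ridit(index, weights)
  q <- as.integer(cut(r, breaks = seq(0, 1, 0.2), include.lowest = TRUE))
  q
}

## ultimate-cluster linearized SE of a weighted proportion: PSU totals of the
## score z_i = w_i (y_i - p), stratified between-PSU variance; single-PSU
## strata contribute zero
ultimate_cluster_se <- function(y, w, strat, psu, p) {
  z <- w * (y - p)
  key <- paste(strat, psu, sep = "\r")
  zt <- tapply(z, key, sum)
  st <- tapply(strat, key, `[`, 1)
  v <- 0
  for (h in unique(st)) {
    zh <- zt[st == h]
    nh <- length(zh)
    if (nh >= 2) v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  sqrt(v) / sum(w)
}

stratum_values <- function(records, level) {
  switch(level,
    national = rep("national", nrow(records)),
    governorate = as.character(records$governorate),
    residence = as.character(records$residence),
    quintile = as.character(records$wealth_quintile),
    stop("unknown stratum level '", level, "'", call. = FALSE))
}

#' Design-weighted coverage estimates
#'
#' Weighted ratio estimator of indicator coverage for every requested
#' (indicator, year, stratum) cell, with design-based standard errors by
#' ultimate-cluster linearization (first-stage clusters as PSUs within the
#' design strata) and the implied effective denominator
#' `n_eff = p(1-p)/SE^2`.  Empty cells are returned flagged `missing`, never
#' silently zero.
#'
#' @param records individual (or household) record table.
#' @param definitions character vector of indicator codes and/or a list of
#'   [indicator_definition()] objects.
#' @param levels aggregation levels, any of `"national"`, `"governorate"`,
#'   `"residence"`, `"quintile"`.
#' @param design an [uhc_design()] descriptor.
#' @return data.frame of class `uhc_coverage` with columns `indicator`,
#'   `year`, `level`, `stratum`, `p`, `se`, `n_eff`, `n`, `pop_share`
#'   (weighted share of the level's population in the stratum), `missing`.
#' @export
estimate_coverage <- function(records, definitions,
                              levels = c("national", "governorate",
                                         "residence", "quintile"),
                              design = uhc_design()) {
  stopifnot(inherits(design, "uhc_design"))
  if (!is.list(definitions) || inherits(definitions, "uhc_indicator"))
    definitions <- as.list(definitions)
  w_all <- records[[design$weight]]
  strat_all <- do.call(paste, c(records[design$strata], sep = "\r"))
  psu_all <- records[[design$psu]]
  years <- sort(unique(records$year))
  out <- list()
  for (def in definitions) {
    m <- indicator_masks(records, def)
    for (yr in years) {
      in_year <- records$year == yr
      for (lev in levels) {
        sv <- stratum_values(records, lev)
        for (s in sort(unique(sv[in_year]))) {
          cell <- in_year & sv == s & m$den
          n <- sum(cell)
          wy <- w_all[in_year & sv == s]
          pop_share <- sum(wy) / sum(w_all[in_year])
          if (n == 0) {
            out[[length(out) + 1L]] <- data.frame(
              indicator = m$name, year = yr, level = lev, stratum = s,
              p = NA_real_, se = NA_real_, n_eff = NA_real_, n = 0L,
              pop_share = pop_share, missing = TRUE)
            next
          }
          y <- as.numeric(m$num[cell])
          w <- w_all[cell]
          p <- sum(w * y) / sum(w)
          se <- ultimate_cluster_se(y, w, strat_all[cell], psu_all[cell], p)
          n_eff <- if (se > 0 && p > 0 && p < 1) p * (1 - p) / se^2 else n
          out[[length(out) + 1L]] <- data.frame(
            indicator = m$name, year = yr, level = lev, stratum = s,
            p = p, se = se, n_eff = max(n_eff, 1), n = n,
            pop_share = pop_share, missing = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("uhc_coverage", "data.frame")
  res
}

#' Financial risk protection: flags and weighted incidence
#'
#' Computes the per-household catastrophic-expenditure and impoverishment
#' flags and their design-weighted incidence by stratum, with
#' ultimate-cluster standard errors.
#'
#' @param hh household record table.
#' @param threshold catastrophic share threshold (strict comparison).
#' @param poverty_line currency per person per day.
#' @param levels aggregation levels as in [estimate_coverage()].
#' @param design an [uhc_design()] descriptor.
#' @param denominator catastrophic denominator, see [flag_catastrophic()].
#' @return list of class `uhc_finprot`: `flags` (the input table plus
#'   logical `catastrophic`, `impoverished`) and `incidence` (a
#'   `uhc_coverage`-shaped table with indicators `CATA` and `IMPOV`).
#' @export
financial_protection <- function(hh, threshold = 0.10, poverty_line = 2.5,
                                 levels = c("national", "governorate",
                                            "residence", "quintile"),
                                 design = uhc_design(),
                                 denominator = "total") {
  hh$catastrophic <- flag_catastrophic(hh, threshold,
                                       denominator = denominator,
                                       poverty_line = poverty_line)
  hh$impoverished <- flag_impoverishment(hh, poverty_line)
  defs <- list(
    indicator_definition("CATA", denominator = function(d) rep(TRUE, nrow(d)),
                         numerator = function(d) d$catastrophic,
                         target = 1e-9),
    indicator_definition("IMPOV", denominator = function(d) rep(TRUE, nrow(d)),
                         numerator = function(d) d$impoverished,
                         target = 1e-9))
  inc <- estimate_coverage(hh, defs, levels = levels, design = design)
  structure(list(flags = hh, incidence = inc,
                 threshold = threshold, poverty_line = poverty_line),
            class = "uhc_finprot")
}

#' @export
print.uhc_finprot <- function(x, ...) {
  nat <- x$incidence[x$incidence$level == "national", ]
  cat(sprintf("Financial risk protection (threshold %.0f%%, line %.2f/person/day)\n",
              100 * x$threshold, x$poverty_line))
  for (i in seq_len(nrow(nat)))
    cat(sprintf("  %-6s %d: %5.1f%% (SE %.1f)\n", nat$indicator[i],
                nat$year[i], 100 * nat$p[i], 100 * nat$se[i]))
  invisible(x)
}
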