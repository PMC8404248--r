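## ---------------------------------------------------------------------------
## Survey readers, column mapping, pipeline orchestration
## ---------------------------------------------------------------------------

#' Column-mapping configuration
#'
#' Maps user columns onto the canonical field names, recodes labelled
#' values onto the canonical categories (e.g. collapsing detailed education
#' labels onto none/primary/secondary/higher/other), and declares
#' missing-value codes.
#'
#' @param columns named character vector/list, canonical name -> user
#'   column.
#' @param recodes named list; each element is a named character vector of
#'   `old value -> canonical value` for one canonical column.
#' @param missing_codes values (in any mapped column) treated as `NA`.
#' @return list of class `uhc_mapping`.
#' @export
column_mapping <- function(columns = NULL, recodes = NULL,
                           missing_codes = NULL) {
  structure(list(columns = columns, recodes = recodes,
                 missing_codes = missing_codes),
            class = "uhc_mapping")
}

#' Read and validate a survey table
#'
#' Reads a CSV, applies an optional column mapping and value recodes, and
#' validates row-level invariants (positive weights; OOP within total
#' consumption for household tables; outcomes only where eligible for
#' individual tables).  Invalid rows are rejected and logged with reasons;
#' more than 5% rejected rows aborts with a summary.
#'
#' @param path CSV path.
#' @param mapping optional [column_mapping()].
#' @param type `"mics"` (individual records) or `"hses"` (household
#'   records).
#' @param max_reject_frac abort threshold on the rejected-row fraction.
#' @return validated data.frame; rejected rows (with a `reason` column) in
#'   `attr(, "rejected")`.
#' @export
read_survey <- function(path, mapping = NULL, type = c("mics", "hses"),
                        max_reject_frac = 0.05) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    stopifnot(inherits(mapping, "uhc_mapping"))
    if (!is.null(mapping$columns)) {
      cols <- unlist(mapping$columns)
      miss <- setdiff(cols, names(df))
      if (length(miss))
        stop("mapped column(s) not in file: ", paste(miss, collapse = ", "),
             call. = FALSE)
      for (canon in names(cols)) df[[canon]] <- df[[cols[[canon]]]]
    }
    if (!is.null(mapping$missing_codes)) {
      for (cn in names(df))
        df[[cn]][df[[cn]] %in% mapping$missing_codes] <- NA
    }
    if (!is.null(mapping$recodes)) {
      for (cn in names(mapping$recodes)) {
        rc <- mapping$recodes[[cn]]
        v <- as.character(df[[cn]])
        hit <- v %in% names(rc)
        v[hit] <- unname(rc[v[hit]])
        df[[cn]] <- v
      }
    }
  }
  reason <- rep(NA_character_, nrow(df))
  if (!is.null(df$weight)) {
    bad <- !is.finite(df$weight) | df$weight <= 0
    reason[bad & is.na(reason)] <- "non-positive weight"
  }
  if (type == "hses") {
    if (all(c("oop", "consumption") %in% names(df))) {
      bad <- !is.na(df$oop) & !is.na(df$consumption) &
        (df$oop > df$consumption | df$oop < 0)
      reason[bad & is.na(reason)] <- "OOP outside [0, consumption]"
    }
  } else {
    ycols <- grep("^y_", names(df), value = TRUE)
    for (yc in ycols) {
      ec <- sub("^y_", "elig_", yc)
      if (!is.null(df[[ec]])) {
        bad <- !is.na(df[[yc]]) & !(df[[ec]] %in% c(TRUE, 1))
        reason[bad & is.na(reason)] <-
          paste0("outcome without eligibility (", yc, ")")
      }
    }
  }
  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!is.na(reason)]
    message(nrow(rejected), " row(s) rejected: ",
            paste(utils::head(unique(rejected$reason), 3), collapse = "; "))
  }
  frac <- nrow(rejected) / max(nrow(df), 1)
  if (frac > max_reject_frac)
    stop(sprintf("%.1f%% of rows rejected (limit %.0f%%); first reasons: %s",
                 100 * frac, 100 * max_reject_frac,
                 paste(utils::head(unique(rejected$reason), 3),
                       collapse = "; ")), call. = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full monitoring pipeline on synthetic or supplied data
#'
#' Executes simulate (optional) -> indicator construction -> equity indices
#' -> trend projection -> determinant models, writes tidy CSV outputs plus a
#' JSON run manifest (config hash, seeds, file checksums), and returns the
#' in-memory bundle.  A stage failure halts with the stage name; outputs of
#' completed stages are preserved on disk.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param mics,hses optional pre-loaded record tables (skips simulation).
#' @param threshold catastrophic-expenditure share threshold.
#' @param trend_indicators indicators to fit trend models for (default the
#'   five service indicators previously found short of the 2030 target).
#' @param trend_level aggregation level for the trend models.
#' @param trend_predictors `"auto"` (default: the subnational IDP and
#'   density series at governorate level, none at the aggregated levels,
#'   where a single national series is collinear with the shared time
#'   trend), `"none"`, or a character vector of predictor variables.
#' @param determinant_outcomes outcomes for the determinant stage.
#' @param horizon projection horizon year.
#' @param trend_mcmc,det_mcmc MCMC settings for the trend and determinant
#'   stages (the trend fits are cheap, so they get the longer chains).
#' @return list of class `uhc_pipeline` with elements `mics`, `hses`,
#'   `coverage`, `finprot`, `equity`, `equity_cata`, `trend` (list of
#'   fits), `attainment`, `determinants` (list of fits), `manifest`,
#'   `files`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("uhc_run_"),
                         mics = NULL, hses = NULL, threshold = 0.10,
                         trend_indicators = c("FPNS", "ANC4", "FULL", "ARI",
                                              "ORT"),
                         trend_level = "quintile",
                         trend_predictors = "auto",
                         determinant_outcomes = "CATA",
                         horizon = 2030,
                         trend_mcmc = list(chains = 2, adapt = 500,
                                           burnin = 1000, iter = 2000),
                         det_mcmc = list(chains = 2, adapt = 300,
                                         burnin = 500, iter = 1000)) {
  stopifnot(inherits(config, "uhc_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mics <- stage("simulate", mics %||% simulate_mics(config))
  hses <- stage("simulate", hses %||% simulate_hses(config))
  predictors <- stage("simulate", simulate_predictors(config))
  files["mics"] <- write_stage_csv(mics, out_dir, "mics_records")
  files["hses"] <- write_stage_csv(hses, out_dir, "hses_records")
  files["predictors"] <- write_stage_csv(predictors, out_dir, "predictors")

  coverage <- stage("indicators",
                    estimate_coverage(mics, uhc_indicators(),
                                      levels = unique(c("national",
                                                        "residence",
                                                        "quintile",
                                                        trend_level))))
  finprot <- stage("indicators",
                   financial_protection(hses, threshold = threshold,
                                        poverty_line = config$poverty_line))
  files["coverage"] <- write_stage_csv(coverage, out_dir, "coverage")
  files["finprot"] <- write_stage_csv(finprot$incidence, out_dir,
                                      "financial_protection")

  eq <- stage("equity", equity_table(coverage))
  eq_cata <- stage("equity", equity_table(finprot$incidence))
  files["equity"] <- write_stage_csv(eq, out_dir, "equity_service")
  files["equity_cata"] <- write_stage_csv(eq_cata, out_dir,
                                          "equity_financial")

  pvars <- if (identical(trend_predictors, "auto")) {
    if (trend_level == "governorate") c("idp", "density") else character(0)
  } else if (identical(trend_predictors, "none")) character(0)
  else trend_predictors
  pred_use <- if (length(pvars))
    predictors[predictors$variable %in% pvars, ] else NULL
  trend <- stage("trend", {
    fits <- lapply(trend_indicators, function(ind)
      fit_trend(coverage, indicator = ind, level = trend_level,
                predictors = pred_use, horizon = horizon,
                chains = trend_mcmc$chains %||% 2,
                adapt = trend_mcmc$adapt %||% 500,
                burnin = trend_mcmc$burnin %||% 1000,
                iter = trend_mcmc$iter %||% 2000,
                seed = fan_seed(config$seed, paste0("trend-", ind))))
    names(fits) <- trend_indicators
    fits
  })
  attainment <- NULL
  if (length(trend)) {
    attainment <- stage("trend", coverage_gap_report(trend, year = horizon))
    files["attainment"] <- write_stage_csv(attainment, out_dir, "attainment")
    proj_all <- do.call(rbind, lapply(trend, `[[`, "projection"))
    files["projections"] <- write_stage_csv(proj_all, out_dir, "projections")
  }

  dets <- stage("determinants", {
    fits <- lapply(as.character(determinant_outcomes), function(oc) {
      rec <- if (oc %in% c("CATA", "IMPOV")) hses
             else mics[mics$year == max(mics$year), ]
      fit_determinants(rec, oc, threshold = threshold,
                       poverty_line = config$poverty_line,
                       chains = det_mcmc$chains %||% 2,
                       adapt = det_mcmc$adapt %||% 300,
                       burnin = det_mcmc$burnin %||% 500,
                       iter = det_mcmc$iter %||% 1000,
                       seed = fan_seed(config$seed, paste0("det-", oc)))
    })
    names(fits) <- determinant_outcomes
    fits
  })
  if (length(dets)) {
    det_tables <- do.call(rbind, lapply(names(dets), function(oc)
      cbind(outcome = oc, dets[[oc]]$or_table)))
    files["determinants"] <- write_stage_csv(det_tables, out_dir,
                                             "determinant_or")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("uhcequity")),
    seed = config$seed,
    stage_seeds = list(mics = fan_seed(config$seed, "mics"),
                       hses = fan_seed(config$seed, "hses"),
                       predictors = fan_seed(config$seed, "predictors")),
    threshold = threshold, poverty_line = config$poverty_line,
    trend_indicators = trend_indicators, trend_level = trend_level,
    horizon = horizon,
    config_hash = unname(tools::md5sum(write_stage_csv(
      data.frame(field = "config",
                 value = paste(deparse(config[setdiff(names(config),
                                                      "indicator_params")]),
                               collapse = "")),
      out_dir, "config_echo"))),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(unname(files))), names(files))),
    timestamp = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  files["manifest"] <- manifest_path

  structure(list(mics = mics, hses = hses, predictors = predictors,
                 coverage = coverage, finprot = finprot, equity = eq,
                 equity_cata = eq_cata, trend = trend,
                 attainment = attainment, determinants = dets,
                 manifest = manifest, files = files, out_dir = out_dir),
            class = "uhc_pipeline")
}

#' @export
print.uhc_pipeline <- function(x, ...) {
  cat("UHC monitoring pipeline run (seed", x$manifest$seed, ")\n")
  cat("  records:", nrow(x$mics), "MICS-like,", nrow(x$hses), "HSES-like\n")
  if (length(x$trend))
    cat("  trend fits:", paste(names(x$trend), collapse = ", "),
        "at", x$trend[[1]]$level, "level\n")
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [sim_config()]; unknown fields are an
#' error.
#'
#' @param path YAML file path.
#' @return a [sim_config()] object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$indicator_params))
    y$indicator_params <- as.data.frame(y$indicator_params)
  do.call(sim_config, y)
}
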