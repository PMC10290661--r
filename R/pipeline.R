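# Orchestration: per-plot estimate assembly in the published 5-column
# schema, availability bookkeeping and design-based summary statistics.

nepal_lon_bounds <- c(80.0, 88.3)
nepal_lat_bounds <- c(26.3, 30.5)

#' Availability bookkeeping over per-plot estimates
#'
#' Counts plots with both pools, AGB only and SOC only, and derives the
#' totals. Rows with neither pool are counted as invalid and reported
#' with a warning, not silently dropped.
#'
#' @param estimates tibble with columns `plot_id`, `agb_t_ha`,
#'   `soc_t_ha` (missing pool encoded as `NA`).
#' @return A list of class `availability_summary` with fields `n_both`,
#'   `n_agb_only`, `n_soc_only`, `n_agb`, `n_soc`, `n_total`,
#'   `n_invalid`.
#' @export
availability_summary <- function(estimates) {
  if (anyDuplicated(estimates$plot_id)) {
    stopf("duplicated plot_id in estimates: %s",
          paste(unique(estimates$plot_id[duplicated(estimates$plot_id)]),
                collapse = ", "))
  }
  has_agb <- !is.na(estimates$agb_t_ha)
  has_soc <- !is.na(estimates$soc_t_ha)
  n_invalid <- sum(!has_agb & !has_soc)
  if (n_invalid > 0) {
    warning(sprintf("%d plot(s) with neither AGB nor SOC", n_invalid),
            call. = FALSE)
  }
  out <- list(
    n_both     = sum(has_agb & has_soc),
    n_agb_only = sum(has_agb & !has_soc),
    n_soc_only = sum(!has_agb & has_soc),
    n_invalid  = n_invalid
  )
  out$n_agb <- out$n_both + out$n_agb_only
  out$n_soc <- out$n_both + out$n_soc_only
  out$n_total <- out$n_both + out$n_agb_only + out$n_soc_only
  structure(out, class = "availability_summary")
}

#' @export
print.availability_summary <- function(x, ...) {
  cat(sprintf(
    "plots: %d total (%d both pools, %d AGB only, %d SOC only)\n",
    x$n_total, x$n_both, x$n_agb_only, x$n_soc_only))
  cat(sprintf("AGB available: %d; SOC available: %d", x$n_agb, x$n_soc))
  if (x$n_invalid > 0) cat(sprintf("; invalid rows: %d", x$n_invalid))
  cat("\n")
  invisible(x)
}

#' Design-based mean and standard error under stratified cluster sampling
#'
#' Plots are the observation units; clusters are the primary sampling
#' units; physiographic regions are the strata. The estimator is the
#' stratum-weighted mean of cluster means (equal stratum weights by
#' default), with the standard error taken from the between-cluster
#' variance of cluster means within each stratum:
#' `se^2 = sum_h W_h^2 * s_h^2 / m_h`, where `s_h^2` is the sample
#' variance of the `m_h` cluster means in stratum `h`. The relative
#' error is `100 * 1.96 * se / mean`, the half-width of the 95%
#' confidence interval as a percentage of the mean.
#'
#' Strata with fewer than two clusters contribute to the mean but are
#' excluded from the variance with a warning.
#'
#' @param values per-plot values of the summarised variable.
#' @param cluster_ids cluster membership of each plot.
#' @param strata stratum of each plot (default: a single stratum).
#' @param weights optional named stratum weights (summing to 1); default
#'   equal weights.
#' @return A list of class `design_summary` with fields `mean`, `se`,
#'   `relative_error_pct`, `n_plots`, `n_clusters`, `n_strata`.
#' @export
cluster_design_summary <- function(values, cluster_ids,
                                   strata = NULL, weights = NULL) {
  ok <- !is.na(values)
  values <- values[ok]
  cluster_ids <- as.character(cluster_ids)[ok]
  strata <- if (is.null(strata)) rep("all", length(values)) else
    as.character(strata)[ok]
  if (length(values) == 0L) stopf("no non-missing values to summarise")
  strat_names <- sort(unique(strata))
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(strat_names),
                                   length(strat_names)), strat_names)
  } else {
    if (!setequal(names(weights), strat_names)) {
      stopf("weights must be named by the strata present")
    }
    weights <- weights[strat_names] / sum(weights)
  }
  mean_total <- 0
  var_total <- 0
  m_total <- 0L
  for (h in strat_names) {
    sel <- strata == h
    cm <- tapply(values[sel], cluster_ids[sel], mean)
    m_h <- length(cm)
    m_total <- m_total + m_h
    mean_total <- mean_total + weights[[h]] * mean(cm)
    if (m_h < 2L) {
      warning(sprintf(
        "stratum '%s' has %d cluster(s); excluded from variance", h, m_h),
        call. = FALSE)
    } else {
      var_total <- var_total + weights[[h]]^2 * stats::var(cm) / m_h
    }
  }
  se <- sqrt(var_total)
  structure(list(mean = mean_total, se = se,
                 relative_error_pct = relative_error_pct(mean_total, se),
                 n_plots = length(values), n_clusters = m_total,
                 n_strata = length(strat_names)),
            class = "design_summary")
}

#' Relative error of a design-based mean at 95% confidence
#'
#' `100 * 1.96 * se / mean`: the half-width of the normal-approximation
#' 95% confidence interval as a percentage of the mean.
#'
#' @param mean estimated mean (nonzero).
#' @param se its standard error.
#' @return Relative error in percent.
#' @examples
#' relative_error_pct(164.76, 6.17) # ~7.34
#' @export
relative_error_pct <- function(mean, se) {
  check_number(se, "se", lower = 0)
  100 * 1.96 * se / mean
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf(
    "mean %.4g, SE %.4g (%.2f%% of mean at 95%% CI); %d plots in %d clusters, %d strata\n",
    x$mean, x$se, x$relative_error_pct, x$n_plots, x$n_clusters,
    x$n_strata))
  invisible(x)
}

# --- published 5-column plot estimate schema -------------------------------

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write per-plot estimates in the published CSV schema
#'
#' Schema (exact header): `plot_id,longitude,latitude,agb_t_ha,soc_t_ha`.
#' Missing pools are written as empty fields (never 0 or a literal
#' "NA"). Numbers are written at fixed 6-decimal precision so that
#' write -> read -> write is byte-identical.
#'
#' @param estimates tibble with the five schema columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plot_estimates <- function(estimates, path) {
  lines <- c("plot_id,longitude,latitude,agb_t_ha,soc_t_ha",
             paste(estimates$plot_id,
                   fmt_num(estimates$longitude),
                   fmt_num(estimates$latitude),
                   fmt_num(estimates$agb_t_ha),
                   fmt_num(estimates$soc_t_ha),
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read per-plot estimates from the published CSV schema
#'
#' Empty fields parse as missing. With `validate_coords = TRUE`
#' (the default, intended for real inventory extracts) coordinates must
#' fall inside Nepal's bounding box (longitude 80.0-88.3, latitude
#' 26.3-30.5); switch off for synthetic fixtures.
#'
#' @param path CSV file path.
#' @param validate_coords check the coordinate bounding box.
#' @return A tibble with columns `plot_id`, `longitude`, `latitude`,
#'   `agb_t_ha`, `soc_t_ha`.
#' @export
read_plot_estimates <- function(path, validate_coords = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(plot_id = "character"),
                        na.strings = "")
  expected <- c("plot_id", "longitude", "latitude", "agb_t_ha", "soc_t_ha")
  if (!identical(names(df), expected)) {
    stopf("%s: expected header %s", path, paste(expected, collapse = ","))
  }
  if (validate_coords) {
    bad <- which(df$longitude < nepal_lon_bounds[1] |
                   df$longitude > nepal_lon_bounds[2] |
                   df$latitude < nepal_lat_bounds[1] |
                   df$latitude > nepal_lat_bounds[2])
    if (length(bad)) {
      stopf("%s: coordinates outside Nepal extent at data line(s) %s",
            path, paste(bad + 1L, collapse = ", "))
    }
  }
  tibble::as_tibble(df)
}

#' Run the full plot-estimation pipeline
#'
#' From an inventory (a list with `species`, `plots`, `trees`, `soil`
#' tibbles, as produced by [gen_inventory()] or [read_inventory_csv()]),
#' computes per-plot AGB and SOC, outer-joins them on `plot_id` with the
#' plot coordinates, and returns the published 5-column estimate table
#' plus the availability summary. One log line per stage reports counts
#' in, filtered and out, so filtering is auditable.
#'
#' @param inventory list of input tibbles; `soil` and/or `trees` may be
#'   absent or cover only some plots (the missing pool is `NA`).
#' @param design a [ccsp_design()].
#' @param spec a [corer_spec()].
#' @param correction Walkley-Black correction factor.
#' @param out optional path; when given, the estimate table is written
#'   there via [write_plot_estimates()].
#' @param fallback allow species fallback (see [plot_agb()]).
#' @param quiet suppress log messages.
#' @return A list with `estimates` (tibble `plot_id`, `longitude`,
#'   `latitude`, `agb_t_ha`, `soc_t_ha`) and `availability`.
#' @export
run_pipeline <- function(inventory, design = ccsp_design(),
                         spec = corer_spec(), correction = 1.33,
                         out = NULL, fallback = TRUE, quiet = FALSE) {
  log1 <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  plots <- inventory$plots
  if (is.null(plots) || anyDuplicated(plots$plot_id)) {
    stopf("inventory$plots must be present with unique plot_id")
  }
  est <- tibble::tibble(plot_id = plots$plot_id,
                        longitude = plots$longitude,
                        latitude = plots$latitude)
  if (!is.null(inventory$trees) && nrow(inventory$trees)) {
    tree_plots <- intersect(plots$plot_id, unique(inventory$trees$plot_id))
    agb <- agb_by_plot(inventory$trees, inventory$species, design,
                       plot_ids = tree_plots, fallback = fallback)
    log1("agb: %d tree records in, %d filtered, %d plots out",
         nrow(inventory$trees), sum(agb$n_filtered), nrow(agb))
    est <- dplyr::left_join(est, agb[, c("plot_id", "agb_t_ha")],
                            by = "plot_id")
  } else {
    est$agb_t_ha <- NA_real_
    log1("agb: no tree records")
  }
  if (!is.null(inventory$soil) && nrow(inventory$soil)) {
    soc <- soc_by_plot(inventory$soil, spec = spec, correction = correction)
    log1("soc: %d layer samples in, %d plots out",
         nrow(inventory$soil), nrow(soc))
    est <- dplyr::left_join(est, soc, by = "plot_id")
  } else {
    est$soc_t_ha <- NA_real_
    log1("soc: no soil samples")
  }
  avail <- suppressWarnings(availability_summary(est))
  log1("plots: %d total, %d both, %d AGB only, %d SOC only, %d empty",
       nrow(est), avail$n_both, avail$n_agb_only, avail$n_soc_only,
       avail$n_invalid)
  if (!is.null(out)) {
    write_plot_estimates(est, out)
    log1("wrote %s (%d rows)", out, nrow(est))
  }
  list(estimates = est, availability = avail)
}
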