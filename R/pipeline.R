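COHORT_SCHEMA_VERSION <- "1"

method_labels <- c(gmm_pet = "gmm_pet", suv25 = "suv_fixed",
                   suv42 = "suv_percent_max")

#' Run the full per-lesion analysis
#'
#' Computes the perfusion-insensitive ADC map, runs each configured
#' segmenter on the cropped SUV map, embeds the masks back on the full
#' grid, and derives ROI biomarkers (area, mean ADC) for every mask plus
#' agreement metrics (Dice, center-of-gravity displacement, normalized to
#' the reference ROI area) against the reference mask. Empty masks produce
#' flagged rows, never failures.
#'
#' @param suv [scalar_slice()] SUV map (full grid).
#' @param dwi [dwi_stack()] on the same grid.
#' @param crop [crop_box()] around the lesion.
#' @param reference [binary_mask()] reference delineation (e.g. a manual
#'   DCE-style ROI), full grid.
#' @param case_id Identifier string for the output rows.
#' @param group Group label (e.g. `"untreated"`/`"treated"`).
#' @param methods Segmentation methods to run, subset of
#'   `c("gmm_pet", "suv25", "suv42")`.
#' @param b_min Minimum b-value for the ADC fit (default 200 s/mm^2).
#' @param seed,n_restarts,tol,max_iter GMM hyperparameters, passed to
#'   [segment_gmm()].
#' @param fixed_t Fixed SUV threshold for `suv25` (default 2.5).
#' @param percent_frac Fraction of maximum for `suv42` (default 0.42).
#' @return A data frame (one row per method plus one `reference` row) with
#'   columns `schema_version, case_id, group, method, threshold, n_voxels,
#'   area_cm2, mean_adc, dice, cog_mm, cog_normalized, flags`.
#' @export
run_case <- function(suv, dwi, crop, reference,
                     case_id = "case", group = NA_character_,
                     methods = c("gmm_pet", "suv25", "suv42"),
                     b_min = 200, seed = 1L, n_restarts = 5L,
                     tol = 1e-6, max_iter = 500L,
                     fixed_t = 2.5, percent_frac = 0.42) {
  stopifnot(inherits(suv, "scalar_slice"), inherits(dwi, "dwi_stack"),
            inherits(crop, "crop_box"), inherits(reference, "binary_mask"))
  methods <- match.arg(methods, several.ok = TRUE)
  stop_if_grid_mismatch(suv, reference)

  adc <- fit_adc(dwi, b_min = b_min)
  cropped <- crop_slice(suv, crop)
  shape <- dim(suv$values)

  ref_m <- roi_metrics(reference, adc)

  row_for <- function(method, mask_full, threshold, flags) {
    rm <- roi_metrics(mask_full, adc)
    ov <- cog_displacement(mask_full, reference,
                           area_ref_cm2 = ref_m$area_cm2)
    data.frame(schema_version = COHORT_SCHEMA_VERSION,
               case_id = case_id, group = group, method = method,
               threshold = if (is.null(threshold)) NA_real_ else threshold,
               n_voxels = rm$n_voxels, area_cm2 = rm$area_cm2,
               mean_adc = rm$mean_adc,
               dice = ov$dice, cog_mm = ov$cog_mm,
               cog_normalized = ov$cog_normalized,
               flags = paste(unique(c(flags, rm$flags, ov$flags)),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  }

  rows <- list(data.frame(schema_version = COHORT_SCHEMA_VERSION,
                          case_id = case_id, group = group,
                          method = "reference", threshold = NA_real_,
                          n_voxels = ref_m$n_voxels,
                          area_cm2 = ref_m$area_cm2,
                          mean_adc = ref_m$mean_adc,
                          dice = 1, cog_mm = 0, cog_normalized = 0,
                          flags = paste(ref_m$flags, collapse = ";"),
                          stringsAsFactors = FALSE))
  for (m in methods) {
    seg <- switch(m,
      gmm_pet = segment_gmm(cropped, seed = seed, n_restarts = n_restarts,
                            tol = tol, max_iter = max_iter),
      suv25 = segment_fixed(cropped, t = fixed_t),
      suv42 = segment_percent_max(cropped, frac = percent_frac))
    full <- uncrop_mask(seg$mask, crop, shape, origin = suv$origin)
    rows[[length(rows) + 1L]] <- row_for(seg$method, full, seg$threshold,
                                         seg$flags)
  }
  do.call(rbind, rows)
}

#' Run a synthetic cohort end to end
#'
#' Simulates a phantom cohort, analyses every case with [run_case()], and
#' assembles the statistical report: per method, paired t tests and
#' Pearson correlations of area and mean ADC against the reference, Welch
#' two-sample t tests between untreated and treated groups for every
#' metric, with Benjamini-Hochberg adjustment across the whole emitted
#' family. Deterministic given `seed`.
#'
#' @param n_untreated,n_treated Group sizes (defaults 24 and 29).
#' @param base_spec Base [phantom_spec()] for the simulator.
#' @param seed Master seed for simulation and GMM fitting.
#' @param methods Segmentation methods to run.
#' @param ... Passed to [simulate_cohort()] (jitter settings, `f_range`).
#' @return A list of class `cohort_run`: `cases` (long per-case table),
#'   `report` (tests with raw and BH-adjusted p), `summary` (per
#'   group x method means and ranges), `manifest`.
#' @export
run_cohort <- function(n_untreated = 24L, n_treated = 29L,
                       base_spec = phantom_spec(
                         dce_jitter_mm = 1, dce_offset_mm = 0.5),
                       seed = 1L,
                       methods = c("gmm_pet", "suv25", "suv42"), ...) {
  cohort <- simulate_cohort(n_untreated, n_treated, base_spec = base_spec,
                            seed = seed, ...)
  gmm_seeds <- withr::with_seed(seed + 1L, {
    sample.int(.Machine$integer.max - 1L,
               length(cohort$cases))
  })
  rows <- lapply(seq_along(cohort$cases), function(i) {
    cs <- cohort$cases[[i]]
    run_case(cs$suv, cs$dwi, cs$crop, cs$reference,
             case_id = cohort$manifest$case_id[i],
             group = cohort$manifest$group[i],
             methods = methods, seed = gmm_seeds[i])
  })
  cases <- do.call(rbind, rows)
  report <- cohort_report(cases)
  summary <- cohort_summary(cases)
  structure(list(cases = cases, report = report, summary = summary,
                 manifest = cohort$manifest), class = "cohort_run")
}

wide_metric <- function(cases, metric) {
  ref <- cases[cases$method == "reference", c("case_id", "group", metric)]
  names(ref)[3] <- "reference"
  ref
}

#' Statistical report over a per-case results table
#'
#' Emits, per segmentation method: paired t and Pearson correlation of
#' area and mean ADC against the reference rows, and Welch two-sample
#' untreated-vs-treated tests of area, mean ADC, Dice and CoG. All raw p
#' values from one invocation form the Benjamini-Hochberg family.
#'
#' @param cases Long table as produced by [run_case()]/[run_cohort()].
#' @return Data frame with columns `method, metric, test, n, statistic,
#'   estimate, p, p_adj, flags`.
#' @export
cohort_report <- function(cases) {
  methods <- setdiff(unique(cases$method), "reference")
  out <- list()
  add <- function(method, metric, test, sr) {
    out[[length(out) + 1L]] <<- data.frame(
      method = method, metric = metric, test = test, n = sr$n,
      statistic = sr$statistic, estimate = sr$estimate, p = sr$p,
      flags = paste(sr$flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  for (m in methods) {
    mm <- cases[cases$method == m, ]
    rf <- cases[cases$method == "reference", ]
    rf <- rf[match(mm$case_id, rf$case_id), ]
    for (metric in c("area_cm2", "mean_adc")) {
      x <- rf[[metric]]; y <- mm[[metric]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) >= 3 && sd(x[keep]) > 0 && sd(y[keep]) > 0) {
        add(m, metric, "paired_t_vs_reference", paired_t(x[keep], y[keep]))
        add(m, metric, "pearson_vs_reference", pearson(x[keep], y[keep]))
      }
    }
    for (metric in c("area_cm2", "mean_adc", "dice", "cog_mm")) {
      u <- mm[[metric]][mm$group == "untreated"]
      t_ <- mm[[metric]][mm$group == "treated"]
      u <- u[is.finite(u)]; t_ <- t_[is.finite(t_)]
      if (length(u) >= 2 && length(t_) >= 2 && (sd(u) > 0 || sd(t_) > 0))
        add(m, metric, "untreated_vs_treated", two_sample_t(u, t_))
    }
  }
  rep <- do.call(rbind, out)
  rep$p_adj <- bh_adjust(rep$p)
  rep[, c("method", "metric", "test", "n", "statistic", "estimate",
          "p", "p_adj", "flags")]
}

#' Group-wise summary of a per-case results table
#'
#' Mean and range of area, mean ADC, Dice and CoG per group and method,
#' in the style of a cohort characteristics table.
#'
#' @param cases Long table as produced by [run_cohort()].
#' @return Data frame with one row per group x method x metric.
#' @export
cohort_summary <- function(cases) {
  metrics <- c("area_cm2", "mean_adc", "dice", "cog_mm", "cog_normalized")
  groups <- list(untreated = "untreated", treated = "treated",
                 all = unique(cases$group))
  out <- list()
  for (g in names(groups)) {
    sub <- cases[cases$group %in% groups[[g]], ]
    for (m in unique(sub$method)) {
      mm <- sub[sub$method == m, ]
      for (metric in metrics) {
        v <- mm[[metric]][is.finite(mm[[metric]])]
        out[[length(out) + 1L]] <- data.frame(
          group = g, method = m, metric = metric, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          range = if (length(v)) diff(range(v)) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.cohort_run <- function(x, ...) {
  n_cases <- length(unique(x$cases$case_id))
  cat(sprintf("<cohort_run> %d cases (%d rows), %d tests in report\n",
              n_cases, nrow(x$cases), nrow(x$report)))
  dsum <- x$summary[x$summary$metric == "dice" &
                      x$summary$group != "all" &
                      x$summary$method != "reference", ]
  for (i in seq_len(nrow(dsum)))
    cat(sprintf("  mean Dice %-16s %-10s %.3f\n",
                dsum$method[i], dsum$group[i], dsum$mean[i]))
  invisible(x)
}

#' Write the outputs of a cohort run to CSV
#'
#' @param run A `cohort_run`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(run, dir) {
  stopifnot(inherits(run, "cohort_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cases = file.path(dir, "cohort_cases.csv"),
             report = file.path(dir, "cohort_report.csv"),
             summary = file.path(dir, "cohort_summary.csv"),
             manifest = file.path(dir, "cohort_manifest.csv"))
  write.csv(run$cases, paths["cases"], row.names = FALSE)
  write.csv(run$report, paths["report"], row.names = FALSE)
  write.csv(run$summary, paths["summary"], row.names = FALSE)
  write.csv(run$manifest, paths["manifest"], row.names = FALSE)
  invisible(paths)
}
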