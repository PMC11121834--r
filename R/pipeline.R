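#' Study configuration
#'
#' Bundles a cohort configuration with reference thresholds and output
#' options.  Two named scenarios are provided: `"realistic"` (measurement
#' noise, per-subject shape jitter, outflow-tract fraction ~0.10 — the
#' realistic regime in which CPF overestimates volumes and underestimates
#' EF) and `"ideal"` (no noise, no jitter, no outflow tract, shapes
#' calibrated to 1.21 — the regime in which CPF is exact and only
#' rasterization error separates the methods).
#'
#' @param scenario `"realistic"` or `"ideal"`; ignored if `cohort` is given.
#' @param n number of subjects.
#' @param seed integer seed (mandatory).
#' @param cohort optional explicit [cohort_config()] overriding the scenario.
#' @param thresholds an [reference_thresholds()] object.
#' @param out_dir optional output directory for result files.
#' @param export_masks write per-subject mask stacks as plain-text files.
#' @param export_plots write scatter / Bland-Altman / ROC plots (PNG).
#' @return An object of class `rv_study_config`.
#' @export
study_config <- function(scenario = c("realistic", "ideal"), n = 70, seed,
                         cohort = NULL,
                         thresholds = reference_thresholds(),
                         out_dir = NULL, export_masks = FALSE,
                         export_plots = FALSE) {
  scenario <- match.arg(scenario)
  if (missing(seed) && is.null(cohort)) stop("'seed' is mandatory")
  if (is.null(cohort)) {
    cohort <- if (scenario == "ideal") ideal_config(n, seed)
              else cohort_config(n, seed)
  }
  structure(list(cohort = cohort, thresholds = thresholds,
                 scenario = scenario, out_dir = out_dir,
                 export_masks = export_masks, export_plots = export_plots),
            class = "rv_study_config")
}

# Internal: tiny polynomial rolling hash for config provenance
# (kept in double precision; 2^31 modulus avoids integer overflow).
config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_json <- function(config) {
  co <- config$cohort
  flat <- unclass(co)
  flat$shape_ed <- unclass(co$shape_ed)
  flat$shape_es <- unclass(co$shape_es)
  as.character(jsonlite::toJSON(list(
    scenario = config$scenario, cohort = flat,
    thresholds = unclass(config$thresholds)), auto_unbox = TRUE, digits = NA))
}

# Internal: quantify one cohort with both methods.
quantify_cohort <- function(cohort, config) {
  co <- attr(cohort, "config")
  n <- nrow(cohort)
  std_edv <- std_esv <- cpf_edv <- cpf_esv <- numeric(n)
  for (i in seq_len(n)) {
    pair <- phantom_pair(cohort[i, ])
    st_ed <- rasterize_short_axis(pair$ed, co$slice_thickness, co$pixel_size,
                                  phase = "ED")
    st_es <- rasterize_short_axis(pair$es, co$slice_thickness, co$pixel_size,
                                  phase = "ES")
    std_edv[i] <- disk_summation_volume(st_ed)$volume_ml
    std_esv[i] <- disk_summation_volume(st_es)$volume_ml
    meas <- simulate_measurements(cohort[i, ], co$noise_sd,
                                  n_observers = 1, n_replicates = 1,
                                  seed = co$seed + 10000L + i)
    cpf_edv[i] <- cpf_volume(meas$Dd_cm, meas$Ld_cm)
    cpf_esv[i] <- cpf_volume(meas$Ds_cm, meas$Ls_cm)
  }
  base <- cohort[, c("id", "sex", "bsa_m2")]
  rbind(
    cbind(base, method_results(cohort$id, "standard", std_edv, std_esv,
                               cohort$bsa_m2)[, -1]),
    cbind(base, method_results(cohort$id, "cpf", cpf_edv, cpf_esv,
                               cohort$bsa_m2)[, -1]))
}

# Internal: CPF re-readings for the reliability sub-study
# (observer 1 twice, observer 2 once, per subject).
reliability_ratings <- function(cohort, config) {
  co <- attr(cohort, "config")
  n_rel <- min(30L, nrow(cohort))
  rows <- vector("list", n_rel)
  for (i in seq_len(n_rel)) {
    meas <- simulate_measurements(cohort[i, ], co$noise_sd,
                                  n_observers = 2, n_replicates = 2,
                                  seed = co$seed + 20000L + i,
                                  observer_bias = c(0, co$observer2_bias))
    pick <- function(obs, rep) meas[meas$observer == obs & meas$replicate == rep, ]
    one <- function(rating, m) {
      edv <- cpf_volume(m$Dd_cm, m$Ld_cm)
      esv <- cpf_volume(m$Ds_cm, m$Ls_cm)
      data.frame(id = cohort$id[i], rating = rating, edv_ml = edv,
                 esv_ml = esv, ef_pct = ejection_fraction(edv, esv),
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(one("obs1_a1", pick(1, 1)),
                       one("obs1_a2", pick(1, 2)),
                       one("obs2", pick(2, 1)))
  }
  do.call(rbind, rows)
}

write_csv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.csv(df, con, row.names = FALSE)
}

report_to_list <- function(report) {
  list(n_subjects = report$n_subjects,
       agreement = report$agreement,
       roc = report$roc,
       reliability = report$reliability)
}

#' Run the full simulated method-comparison study
#'
#' Simulate a cohort, rasterize every subject's end-diastolic and
#' end-systolic phantom into short-axis mask stacks, quantify each subject
#' with disk summation (standard method) and with the cone-pyramid formula
#' from noisy four-chamber measurements, classify against sex-specific
#' reference thresholds, and assemble the method-comparison report,
#' including an observer-reliability sub-study of up to 30 subjects.
#' Reruns with the same configuration are value-identical.
#'
#' @param config an [study_config()] object.
#' @return An object of class `rv_study`: `cohort`, `results`, `reliability`,
#'   `report`, `config`, `config_hash`.  If `config$out_dir` is set, writes
#'   `cohort.csv`, `results.csv`, `reliability.csv`, `agreement.csv`,
#'   `roc.csv`, `reliability_table.csv`, `report.json`, `config.json` and
#'   `log.txt` there (CSV headers carry the config hash as a `#` comment
#'   line).
#' @export
run_study <- function(config) {
  if (!inherits(config, "rv_study_config"))
    stop("'config' must be an rv_study_config")
  cj <- config_json(config)
  hash <- config_hash(cj)
  cohort <- sample_cohort(config$cohort)
  results <- quantify_cohort(cohort, config)
  reliability <- reliability_ratings(cohort, config)
  report <- build_comparison_report(results, reliability, config$thresholds)
  study <- structure(list(cohort = cohort, results = results,
                          reliability = reliability, report = report,
                          config = config, config_hash = hash),
                     class = "rv_study")
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' @export
print.rv_study <- function(x, ...) {
  cat(sprintf("Simulated RV method-comparison study (scenario: %s, seed %d, hash %s)\n\n",
              x$config$scenario, x$config$cohort$seed, x$config_hash))
  print(x$report)
  invisible(x)
}

#' Write study result files
#'
#' @param study an [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# rvcpf %s scenario=%s seed=%d config=%s",
                   as.character(utils::packageVersion("rvcpf")),
                   study$config$scenario, study$config$cohort$seed,
                   study$config_hash)
  p <- function(f) file.path(out_dir, f)
  write_csv_stamped(as.data.frame(study$cohort), p("cohort.csv"), stamp)
  write_csv_stamped(study$results, p("results.csv"), stamp)
  write_csv_stamped(study$reliability, p("reliability.csv"), stamp)
  write_csv_stamped(study$report$agreement, p("agreement.csv"), stamp)
  write_csv_stamped(study$report$roc, p("roc.csv"), stamp)
  write_csv_stamped(study$report$reliability, p("reliability_table.csv"), stamp)
  jsonlite::write_json(c(list(config_hash = study$config_hash),
                         report_to_list(study$report)),
                       p("report.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(config_json(study$config), p("config.json"))
  n <- nrow(study$cohort)
  cls <- classify_rv(study$cohort$sex,
                     study$results$edvi[study$results$method == "standard"],
                     study$results$esvi[study$results$method == "standard"],
                     study$results$ef_pct[study$results$method == "standard"],
                     study$config$thresholds)
  log <- c(stamp,
           sprintf("subjects simulated: %d", n),
           sprintf("mask stacks rasterized: %d", 2L * n),
           sprintf("flagged enlarged RV (EDV index): %d", sum(cls$enlarged_edv)),
           sprintf("flagged enlarged RV (ESV index): %d", sum(cls$enlarged_esv)),
           sprintf("flagged reduced RV function: %d", sum(cls$reduced_ef)))
  writeLines(log, p("log.txt"))
  if (isTRUE(study$config$export_masks)) export_masks(study, p("masks"))
  if (isTRUE(study$config$export_plots)) export_plots(study, out_dir)
  invisible(list.files(out_dir, full.names = TRUE))
}

# Internal: plain-text mask export (one file per subject-phase; rows of 0/1).
export_masks <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- attr(study$cohort, "config")
  for (i in seq_len(nrow(study$cohort))) {
    pair <- phantom_pair(study$cohort[i, ])
    for (phase in c("ED", "ES")) {
      g <- if (phase == "ED") pair$ed else pair$es
      st <- rasterize_short_axis(g, co$slice_thickness, co$pixel_size, phase)
      path <- file.path(dir, sprintf("%s_%s.txt", study$cohort$id[i], phase))
      con <- file(path, "w")
      writeLines(sprintf("# pixel_size=%g slice_thickness=%g phase=%s",
                         st$pixel_size, st$slice_thickness, phase), con)
      for (s in seq_along(st$masks)) {
        writeLines(sprintf("# slice %d", s), con)
        utils::write.table(st$masks[[s]], con, row.names = FALSE,
                           col.names = FALSE)
      }
      close(con)
    }
  }
}

# Internal: diagnostic plots with base graphics.
export_plots <- function(study, out_dir) {
  ag <- study$report$agreement
  res <- study$results
  std <- res[res$method == "standard", ]
  cpf <- res[res$method == "cpf", ]
  cpf <- cpf[match(std$id, cpf$id), ]
  quantities <- list(edvi = "RV-EDV index (mL/m2)",
                     esvi = "RV-ESV index (mL/m2)",
                     ef_pct = "RV-EF (%)")
  grDevices::png(file.path(out_dir, "agreement_plots.png"),
                 width = 1400, height = 900, res = 120)
  op <- graphics::par(mfrow = c(2, 3))
  on.exit({graphics::par(op); grDevices::dev.off()})
  for (q in names(quantities)) {
    plot_method_scatter(std[[q]], cpf[[q]], quantities[[q]])
  }
  for (q in names(quantities)) {
    plot_bland_altman(bland_altman(std[[q]], cpf[[q]]), quantities[[q]])
  }
  invisible(NULL)
}

#' Scatter plot of two methods with regression line
#'
#' @param x,y paired standard-method and CPF values.
#' @param label axis label.
#' @export
plot_method_scatter <- function(x, y, label = "value") {
  graphics::plot(x, y, xlab = paste("standard:", label),
                 ylab = paste("CPF:", label), pch = 16,
                 col = grDevices::grey(0.3))
  graphics::abline(stats::lm(y ~ x), col = "firebrick", lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}

#' Bland-Altman plot
#'
#' @param ba an [bland_altman()] result.
#' @param label quantity label.
#' @export
plot_bland_altman <- function(ba, label = "value") {
  graphics::plot(ba$means, ba$differences, pch = 16,
                 col = grDevices::grey(0.3),
                 xlab = paste("mean of methods:", label),
                 ylab = "standard - CPF")
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2), col = "firebrick")
  invisible(NULL)
}

#' ROC curve plot
#'
#' @param roc an [roc_auc()] result.
#' @param label target label.
#' @export
plot_roc <- function(roc, label = "") {
  tab <- roc$thresholds[order(1 - roc$thresholds$specificity,
                              roc$thresholds$sensitivity), ]
  graphics::plot(1 - tab$specificity, tab$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1), lwd = 2,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s AUC = %.3f", label, roc$auc))
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
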