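#' Pearson correlation of paired method measurements
#'
#' Standard product-moment correlation with the two-sided p-value from the
#' t transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors (e.g. standard-method and CPF values).
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in one variable")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are computed as `x - y` (by convention: standard method minus
#' CPF).  Limits of agreement are `bias +/- 1.96 * sd` of the differences.
#'
#' @param x,y paired numeric vectors.
#' @return An object of class `rv_bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, `differences`, `means`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), differences = d, means = (x + y) / 2),
            class = "rv_bland_altman")
}

#' @export
print.rv_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f (SD %.3f), 95%% LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Mean and SD of paired differences
#'
#' The "difference" column convention of method-comparison tables: the mean
#' of elementwise differences always equals the difference of the two method
#' means, so the column can be recomputed from the printed means.
#'
#' @param x,y paired numeric vectors; differences are `x - y`.
#' @return A list: `mean`, `sd`, `n`, `formatted` (`"m +/- s"` at one
#'   decimal).
#' @export
paired_diff_summary <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  list(mean = mean(d), sd = stats::sd(d), n = length(d),
       formatted = sprintf("%.1f ± %.1f", mean(d), stats::sd(d)))
}

#' ROC curve analysis with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties count one half),
#' computed together with its DeLong standard error and 95% CI via the pROC
#' package.  The threshold table uses observed-value criteria: for
#' `direction = "higher"` a case is called positive when `score > t`
#' (rendered `">t"`), for `direction = "lower"` when `score <= t`
#' (rendered `"<=t"`).
#'
#' @param scores numeric predictor values.
#' @param labels class labels (logical or 0/1; 1 = positive).
#' @param direction `"higher"` if positives have higher scores, `"lower"`
#'   otherwise.
#' @return An object of class `rv_roc`: `auc`, `se`, `ci95` (clipped to
#'   [0, 1]), `direction`, `thresholds` (data.frame with `threshold`,
#'   `sensitivity`, `specificity`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  lab <- as.integer(as.logical(labels))
  if (length(scores) != length(lab)) stop("'scores'/'labels' length mismatch")
  if (length(unique(lab)) < 2)
    stop("both classes must be present for ROC analysis")
  r <- pROC::roc(response = lab, predictor = scores, levels = c(0, 1),
                 direction = if (direction == "higher") "<" else ">",
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # AUC = 1 yields SE 0 and CI [1, 1]; pROC warns about it, we document it
  se <- suppressWarnings(sqrt(pROC::var(r, method = "delong")))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  ci <- pmin(pmax(ci, 0), 1)
  pos <- scores[lab == 1]; neg <- scores[lab == 0]
  tt <- sort(unique(scores))
  if (direction == "higher") {
    thr <- c(-Inf, tt)
    sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  } else {
    thr <- c(-Inf, tt)  # "<= -Inf" calls nothing positive
    sens <- vapply(thr, function(t) mean(pos <= t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg > t), numeric(1))
  }
  structure(list(auc = auc, se = se, ci95 = ci, direction = direction,
                 thresholds = data.frame(threshold = thr,
                                         sensitivity = sens,
                                         specificity = spec),
                 n_pos = length(pos), n_neg = length(neg)),
            class = "rv_roc")
}

#' @export
print.rv_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal cut-off by the Youden index
#'
#' Selects the threshold maximizing `J = sensitivity + specificity - 1`.
#' Ties are broken toward higher sensitivity, then toward the lower
#' threshold.  The criterion is rendered in the observed-value style
#' (`">99.4"` for higher-is-positive, `"<=40"` for lower-is-positive).
#'
#' @param roc an [roc_auc()] result.
#' @return A list of class `rv_cutoff`: `cutoff`, `criterion`,
#'   `sensitivity_pct`, `specificity_pct`, `youden_j` (0-1 scale).
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "rv_roc")) stop("'roc' must be an rv_roc object")
  tab <- roc$thresholds
  j <- tab$sensitivity + tab$specificity - 1
  best <- order(-j, -tab$sensitivity, tab$threshold)[1]
  cut <- tab$threshold[best]
  crit <- if (roc$direction == "higher")
    sprintf(">%g", cut) else sprintf("<=%g", cut)
  structure(list(cutoff = cut, criterion = crit,
                 sensitivity_pct = 100 * tab$sensitivity[best],
                 specificity_pct = 100 * tab$specificity[best],
                 youden_j = j[best]),
            class = "rv_cutoff")
}

#' @export
print.rv_cutoff <- function(x, ...) {
  cat(sprintf("Cut-off %s: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
              x$criterion, x$sensitivity_pct, x$specificity_pct, x$youden_j))
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, the usual choice for
#' intra-/inter-observer agreement of quantitative measurements: both
#' subjects and raters are random effects and systematic rater offsets count
#' against agreement.  Computed from the two-way ANOVA mean squares, with the
#' F-based 95% confidence interval.
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, raters in
#'   columns; no missing cells.
#' @return An object of class `rv_icc`: `icc`, `ci95`, `ms` (list with
#'   `rows`, `cols`, `error`), `n`, `k`, `model`.
#' @export
icc_absolute_single <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("missing cells are not supported")
  if (!is.numeric(m)) stop("'ratings' must be numeric")
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 raters")
  if (n < 5) stop("need at least 5 subjects")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F-based CI (McGraw & Wong 1996, ICC(A,1))
  alpha <- 0.05
  ci <- if (mse <= .Machine$double.eps * grand^2 && msc <= mse) {
    c(icc, icc)  # degenerate: perfect agreement
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    c(lo, hi)
  }
  if (anyNA(ci) || any(!is.finite(ci))) ci <- c(icc, icc)
  structure(list(icc = icc, ci95 = ci,
                 ms = list(rows = msr, cols = msc, error = mse),
                 n = n, k = k,
                 model = "two-way random, absolute agreement, single measures"),
            class = "rv_icc")
}

#' @export
print.rv_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f (95%% CI %.4f-%.4f), n = %d subjects, %d raters\n",
              x$icc, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}

# Internal: one agreement-table row for a quantity measured by both methods.
agreement_row <- function(quantity, units, std, cpf) {
  ba <- bland_altman(std, cpf)
  r <- p <- NA_real_
  if (length(std) >= 3 && stats::sd(std) > 0 && stats::sd(cpf) > 0) {
    pr <- pearson_r(std, cpf)
    r <- pr$r; p <- pr$p
  }
  data.frame(quantity = quantity, units = units,
             mean_standard = mean(std), sd_standard = stats::sd(std),
             mean_cpf = mean(cpf), sd_cpf = stats::sd(cpf),
             diff_mean = ba$bias, diff_sd = ba$sd,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             r = r, p = p, n = ba$n,
             stringsAsFactors = FALSE)
}

# Internal: one ROC-summary row; NA row when only one class is present.
roc_row <- function(target, scores, labels, direction) {
  if (length(unique(as.integer(as.logical(labels)))) < 2) {
    return(data.frame(target = target, n_pos = sum(as.logical(labels)),
                      n_neg = sum(!as.logical(labels)),
                      auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      criterion = NA_character_, sensitivity_pct = NA_real_,
                      specificity_pct = NA_real_, youden_j = NA_real_,
                      stringsAsFactors = FALSE))
  }
  roc <- roc_auc(scores, labels, direction)
  cut <- youden_cutoff(roc)
  data.frame(target = target, n_pos = roc$n_pos, n_neg = roc$n_neg,
             auc = roc$auc, ci_low = roc$ci95[1], ci_high = roc$ci95[2],
             criterion = cut$criterion,
             sensitivity_pct = cut$sensitivity_pct,
             specificity_pct = cut$specificity_pct,
             youden_j = cut$youden_j,
             stringsAsFactors = FALSE)
}

# Internal: reliability rows (per-rater mean +/- SD, paired diff, ICC).
reliability_rows <- function(reliability, quantity_col, quantity) {
  wide <- function(rating) {
    sub <- reliability[reliability$rating == rating, ]
    sub[[quantity_col]][order(sub$id)]
  }
  a1 <- wide("obs1_a1"); a2 <- wide("obs1_a2"); o2 <- wide("obs2")
  one <- function(comparison, first, second) {
    d <- paired_diff_summary(second, first)  # second minus first analysis
    icc <- icc_absolute_single(cbind(first, second))
    data.frame(quantity = quantity, comparison = comparison,
               mean_first = mean(first), sd_first = stats::sd(first),
               mean_second = mean(second), sd_second = stats::sd(second),
               diff_mean = d$mean, diff_sd = d$sd,
               icc = icc$icc, icc_low = icc$ci95[1], icc_high = icc$ci95[2],
               n = length(first), stringsAsFactors = FALSE)
  }
  rbind(one("intraobserver", a1, a2), one("interobserver", a1, o2))
}

#' Build the cohort-level method-comparison report
#'
#' Assembles (a) an agreement table — per quantity (EDV index, ESV index,
#' EF): mean and SD for both methods, paired difference (standard minus CPF),
#' limits of agreement, Pearson r — (b) ROC/cut-off rows for the detection of
#' an enlarged RV (EDV index, ESV index) and reduced RV function (EF) by the
#' CPF values against the standard-method classification, and (c) an optional
#' observer-reliability table (per-rater mean and SD, paired differences,
#' ICC with 95% CI).
#'
#' @param results long data.frame with columns `id`, `sex`, `bsa_m2`,
#'   `method` (`"standard"`/`"cpf"`), `edv_ml`, `esv_ml`, `ef_pct`, `edvi`,
#'   `esvi`; every subject must appear once per method.
#' @param reliability optional data.frame with columns `id`, `rating`
#'   (`"obs1_a1"`, `"obs1_a2"`, `"obs2"`), `edv_ml`, `esv_ml`, `ef_pct`.
#' @param thresholds an [reference_thresholds()] object.
#' @return An object of class `rv_comparison_report` with elements
#'   `agreement`, `roc`, `reliability` (or NULL), `n_subjects`.
#' @export
build_comparison_report <- function(results, reliability = NULL,
                                    thresholds = reference_thresholds()) {
  need <- c("id", "sex", "bsa_m2", "method", "edv_ml", "esv_ml",
            "ef_pct", "edvi", "esvi")
  if (!all(need %in% names(results)))
    stop("results must contain columns: ", paste(need, collapse = ", "))
  std <- results[results$method == "standard", ]
  cpf <- results[results$method == "cpf", ]
  common <- intersect(std$id, cpf$id)
  if (length(common) < 2) stop("need >= 2 subjects with both methods")
  std <- std[match(common, std$id), ]
  cpf <- cpf[match(common, cpf$id), ]
  agreement <- rbind(
    agreement_row("RV-EDV index", "mL/m2", std$edvi, cpf$edvi),
    agreement_row("RV-ESV index", "mL/m2", std$esvi, cpf$esvi),
    agreement_row("RV-EF", "%", std$ef_pct, cpf$ef_pct))
  cls <- classify_rv(std$sex, std$edvi, std$esvi, std$ef_pct, thresholds)
  roc <- rbind(
    roc_row("enlarged RV (EDV index)", cpf$edvi, cls$enlarged_edv, "higher"),
    roc_row("enlarged RV (ESV index)", cpf$esvi, cls$enlarged_esv, "higher"),
    roc_row("reduced RV function (EF)", cpf$ef_pct, cls$reduced_ef, "lower"))
  rel <- NULL
  if (!is.null(reliability)) {
    rel <- rbind(
      reliability_rows(reliability, "edv_ml", "RV-EDV"),
      reliability_rows(reliability, "esv_ml", "RV-ESV"),
      reliability_rows(reliability, "ef_pct", "RV-EF"))
  }
  structure(list(agreement = agreement, roc = roc, reliability = rel,
                 n_subjects = length(common)),
            class = "rv_comparison_report")
}

#' @export
print.rv_comparison_report <- function(x, ...) {
  cat(sprintf("Method-comparison report, n = %d subjects\n\n", x$n_subjects))
  cat("Agreement (standard vs CPF):\n")
  ag <- x$agreement
  for (i in seq_len(nrow(ag)))
    cat(sprintf("  %-14s %6.1f ± %4.1f | %6.1f ± %4.1f | diff %5.1f ± %4.1f | r = %s\n",
                paste0(ag$quantity[i], " (", ag$units[i], ")"),
                ag$mean_standard[i], ag$sd_standard[i],
                ag$mean_cpf[i], ag$sd_cpf[i],
                ag$diff_mean[i], ag$diff_sd[i],
                ifelse(is.na(ag$r[i]), "NA", sprintf("%.3f", ag$r[i]))))
  cat("\nDetection of abnormal RV by CPF (labels: standard method):\n")
  ro <- x$roc
  for (i in seq_len(nrow(ro))) {
    if (is.na(ro$auc[i])) {
      cat(sprintf("  %-26s single class (%d pos / %d neg): no ROC\n",
                  ro$target[i], ro$n_pos[i], ro$n_neg[i]))
    } else {
      cat(sprintf("  %-26s AUC %.3f (%.3f-%.3f), cut-off %s: sens %.1f%%, spec %.1f%%\n",
                  ro$target[i], ro$auc[i], ro$ci_low[i], ro$ci_high[i],
                  ro$criterion[i], ro$sensitivity_pct[i],
                  ro$specificity_pct[i]))
    }
  }
  if (!is.null(x$reliability)) {
    cat("\nObserver reliability (CPF):\n")
    re <- x$reliability
    for (i in seq_len(nrow(re)))
      cat(sprintf("  %-8s %-14s diff %5.1f ± %4.1f, ICC %.4f (%.4f-%.4f)\n",
                  re$quantity[i], re$comparison[i], re$diff_mean[i],
                  re$diff_sd[i], re$icc[i], re$icc_low[i], re$icc_high[i]))
  }
  invisible(x)
}
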