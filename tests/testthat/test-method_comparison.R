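test_that("Pearson correlation matches hand computation and its null", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3))$r, 0.6)
  set.seed(31)
  null <- pearson_r(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(null$r), 0.05)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman recovers bias and SD of differences", {
  x <- c(10, 12, 14)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, -5)
  expect_equal(ba5$sd, 0)
  set.seed(32)
  base <- rnorm(1e4, 100, 20)
  ba <- bland_altman(base + 3 + rnorm(1e4, 0, 2), base)
  expect_lt(abs(ba$bias - 3), 3 * 2 / sqrt(1e4))
  expect_lt(abs(ba$sd - 2), 3 * 2 / sqrt(2e4))
  expect_lte(ba$loa_low, ba$bias)
  expect_lte(ba$bias, ba$loa_high)
  # limits of agreement cover ~95% of Gaussian differences
  cover <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("paired difference summary obeys the difference-of-means identity", {
  set.seed(33)
  x <- rnorm(50, 80, 10); y <- rnorm(50, 85, 12)
  d <- paired_diff_summary(x, y)
  expect_equal(d$mean, mean(x) - mean(y), tolerance = 1e-12)
  expect_equal(d$sd, sd(x - y))
  z <- c(4, 7)
  expect_equal(paired_diff_summary(z, z)$mean, 0)
  expect_equal(paired_diff_summary(z, z)$sd, 0)
})

test_that("AUC equals brute-force pair counting", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), "higher")
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1), "higher")$auc, 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(34)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    dir <- sample(c("higher", "lower"), 1)
    r <- roc_auc(scores, labels, dir)
    expect_equal(r$auc, brute_auc(scores, labels, dir), tolerance = 1e-12)
    expect_true(r$ci95[1] >= 0 && r$ci95[2] <= 1)
  }
  # permuted labels: AUC near 1/2
  set.seed(35)
  null_auc <- roc_auc(rnorm(1000), sample(rep(0:1, 500)), "higher")$auc
  expect_lt(abs(null_auc - 0.5), 0.06)
})

test_that("Youden cut-off maximizes J with the stated tie-breaks", {
  perfect <- youden_cutoff(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1), "higher"))
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)
  # J ties at 0.5; higher sensitivity wins, criterion rendered ">1"
  tie <- youden_cutoff(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1), "higher"))
  expect_equal(tie$youden_j, 0.5)
  expect_equal(tie$sensitivity_pct, 100)
  expect_equal(tie$criterion, ">1")
  # all scores identical: no discrimination
  flat <- youden_cutoff(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1), "higher"))
  expect_equal(flat$youden_j, 0)
  # lower-is-positive renders a "<=" criterion
  low <- youden_cutoff(roc_auc(c(1, 2, 10, 11), c(1, 1, 0, 0), "lower"))
  expect_equal(low$criterion, "<=2")
  expect_equal(low$youden_j, 1)
})

test_that("ICC(A,1) matches its ANOVA identity and external values", {
  set.seed(11)
  subj <- rnorm(12, 100, 20)
  m <- cbind(subj + rnorm(12, 0, 5), subj + 8 + rnorm(12, 0, 5),
             subj - 3 + rnorm(12, 0, 5))
  m <- round(m, 6)
  res <- icc_absolute_single(m)
  # frozen reference value computed independently (pingouin ICC(A,1))
  expect_equal(res$icc, 0.901979038949156, tolerance = 1e-9)
  expect_equal(round(res$ci95, 2), c(0.55, 0.97))
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
  # duplicated rater: perfect agreement
  dup <- icc_absolute_single(cbind(subj, subj))
  expect_equal(dup$icc, 1)
  # constant offset: absolute agreement is penalized below consistency ICC
  off <- icc_absolute_single(cbind(subj, subj + 15))
  consistency <- with(off$ms, (rows - error) / (rows + (2 - 1) * error))
  expect_lt(off$icc, consistency)
  expect_lt(off$icc, 1)
  # independent columns: ICC near zero
  set.seed(36)
  indep <- icc_absolute_single(cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(indep$icc), 0.1)
  expect_error(icc_absolute_single(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
  expect_error(icc_absolute_single(matrix(1:8, 4, 2)), "5 subjects")
})

test_that("ICC recovers known variance components", {
  set.seed(37)
  n <- 4000; k <- 20
  s2_s <- 4; s2_r <- 1; s2_e <- 1
  subj <- rnorm(n, 0, sqrt(s2_s))
  rater <- rnorm(k, 0, sqrt(s2_r))
  m <- outer(subj, rater, `+`) + matrix(rnorm(n * k, 0, sqrt(s2_e)), n, k)
  res <- icc_absolute_single(m)
  expect_equal(res$icc, s2_s / (s2_s + s2_r + s2_e), tolerance = 0.08)
})

test_that("the comparison report assembles agreement, ROC and reliability", {
  set.seed(38)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  sex <- rep(c("male", "female"), length.out = n)
  bsa <- rnorm(n, 1.99, 0.2)
  std_edv <- rnorm(n, 165, 55); std_esv <- std_edv * runif(n, 0.35, 0.75)
  cpf_edv <- std_edv * rnorm(n, 1.05, 0.08)
  cpf_esv <- std_esv * rnorm(n, 1.15, 0.10)
  results <- rbind(
    cbind(data.frame(id = ids, sex = sex, bsa_m2 = bsa),
          method_results(ids, "standard", std_edv, std_esv, bsa)[, -1]),
    cbind(data.frame(id = ids, sex = sex, bsa_m2 = bsa),
          method_results(ids, "cpf", cpf_edv, cpf_esv, bsa)[, -1]))
  rel <- do.call(rbind, lapply(c("obs1_a1", "obs1_a2", "obs2"), function(rt) {
    jit <- if (rt == "obs2") 12 else 0
    edv <- std_edv[1:30] + jit + rnorm(30, 0, 5)
    esv <- std_esv[1:30] + rnorm(30, 0, 4)
    data.frame(id = ids[1:30], rating = rt, edv_ml = edv, esv_ml = esv,
               ef_pct = ejection_fraction(edv, esv))
  }))
  rep <- build_comparison_report(results, rel)
  expect_s3_class(rep, "rv_comparison_report")
  expect_equal(nrow(rep$agreement), 3)
  # difference column equals the difference of the report's own mean columns
  expect_equal(rep$agreement$diff_mean,
               rep$agreement$mean_standard - rep$agreement$mean_cpf,
               tolerance = 1e-12)
  expect_equal(nrow(rep$roc), 3)
  expect_true(all(rep$roc$auc >= 0 & rep$roc$auc <= 1, na.rm = TRUE))
  expect_equal(nrow(rep$reliability), 6)
  expect_true(all(rep$reliability$icc <= 1))
  # interobserver EDV offset should depress the absolute-agreement ICC
  intra_edv <- rep$reliability[rep$reliability$quantity == "RV-EDV" &
                               rep$reliability$comparison == "intraobserver", ]
  inter_edv <- rep$reliability[rep$reliability$quantity == "RV-EDV" &
                               rep$reliability$comparison == "interobserver", ]
  expect_lt(inter_edv$icc, intra_edv$icc)
  # two-subject degenerate input: summaries populated, inference null
  mini <- results[results$id %in% ids[1:2], ]
  rep2 <- build_comparison_report(mini)
  expect_true(all(is.finite(rep2$agreement$mean_standard)))
  expect_true(all(is.na(rep2$agreement$r)))
  expect_null(rep2$reliability)
})
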