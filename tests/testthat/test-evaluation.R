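test_that("time-dependent ROC: degenerate and perfect markers", {
  n <- 40
  time <- c(seq(100, 800, length.out = 20), seq(2000, 4000, length.out = 20))
  event <- rep(1, n)
  # identical scores: uninformative, AUC 1/2
  flat <- time_dependent_roc(rep(3, n), time, event, horizon = 1095)
  expect_equal(flat$auc, 0.5)
  # scores perfectly ordering event-by-horizon status: AUC 1
  score <- c(rep(10, 20), rep(0, 20)) + seq(0.001, 0.04, length.out = n)
  perfect <- time_dependent_roc(score, time, event, horizon = 1095)
  expect_equal(perfect$auc, 1.0)
  expect_error(time_dependent_roc(score, time, event, horizon = 10),
               class = "pairsig_input_error")
})

test_that("uncensored time-dependent AUC equals the binary rank-sum AUC", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 60
    time <- sample(seq(50, 3000, by = 13), n)
    event <- rep(1, n)
    score <- rnorm(n)
    label <- as.integer(time <= 1095)
    if (sum(label) == 0 || sum(label) == n) next
    roc <- time_dependent_roc(score, time, event, 1095)
    expect_lt(abs(roc$auc - brute_binary_auc(score, label)), 1e-12)
  }
})

test_that("AUC is invariant to monotone score transforms; sign flips it", {
  d <- toy_surv(80, seed = 4)
  score <- rnorm(80)
  roc <- time_dependent_roc(score, d$time, d$event, 1000)
  roc_t <- time_dependent_roc(exp(2 * score + 1), d$time, d$event, 1000)
  expect_lt(abs(roc$auc - roc_t$auc), 1e-12)
  # sign flip: exact complement on uncensored data; under censoring the
  # KM-weighted estimator evaluates boundary subgroups one sample apart,
  # so the identity holds only approximately
  roc_u <- time_dependent_roc(score, d$time, rep(1, 80), 1000)
  roc_u_neg <- time_dependent_roc(-score, d$time, rep(1, 80), 1000)
  expect_lt(abs(roc_u$auc - (1 - roc_u_neg$auc)), 1e-10)
  roc_neg <- time_dependent_roc(-score, d$time, d$event, 1000)
  expect_lt(abs(roc$auc - (1 - roc_neg$auc)), 0.02)
})

test_that("Youden cutoff matches the exhaustive sweep on uncensored data", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    time <- sample(seq(30, 2500, by = 11), n)
    event <- rep(1, n)
    score <- round(rnorm(n), 2)   # deliberate score ties
    label <- as.integer(time <= 1095)
    if (length(unique(label)) < 2) next
    roc <- time_dependent_roc(score, time, event, 1095)
    yj <- youden_cutoff(roc)
    bf <- brute_youden(score, label)
    expect_equal(yj$J, bf$J, tolerance = 1e-10)
    expect_equal(yj$cutoff, bf$cutoff)
  }
})

test_that("Youden endpoints: perfect marker J = 1, uninformative J = 0", {
  time <- c(100, 200, 2000, 3000); event <- rep(1, 4)
  perfect <- youden_cutoff(time_dependent_roc(c(9, 8, 1, 2), time, event, 1095))
  expect_equal(perfect$J, 1)
  flat <- youden_cutoff(time_dependent_roc(rep(1, 4), time, event, 1095))
  expect_equal(flat$J, 0)
})

test_that("clinical_cox separates signal from null covariates", {
  co <- generate_cohort(simulation_config(
    n_samples = 600, n_marker_genes = 4, n_background_genes = 0,
    planted_pairs = data.frame(gene_a = "BRG001", gene_b = "BRG002",
                               beta = 1.2),
    censor_rate = 0.2, seed = 41))
  scores <- data.frame(sample_id = co$clinical$sample_id,
                       risk_score = co$truth$linear_predictor)
  class(scores) <- c("risk_scores", "data.frame")
  fit <- clinical_cox(scores, co$clinical)
  expect_true(fit$independent)
  expect_lt(fit$multivariate$p[["risk_score"]], 0.05)
  clin_p <- fit$multivariate$p[names(fit$multivariate$p) != "risk_score"]
  expect_gt(min(clin_p), 0.001)   # survival depends on the score only
  # empty covariate list reduces multivariate to univariate
  fit0 <- clinical_cox(scores, co$clinical, covariates = character(0))
  expect_identical(fit0$univariate$coef, fit0$multivariate$coef)
  # a covariate duplicating the risk group is collinear
  cl2 <- co$clinical
  cl2$dup <- scores$risk_score
  expect_error(clinical_cox(scores, cl2, covariates = c("dup")),
               class = "pairsig_input_error")
})

test_that("chi-square associations match hand arithmetic", {
  mk <- function(gender) {
    n <- length(gender)
    cl <- data.frame(sample_id = paste0("s", 1:n), os_days = 100,
                     event = 1, gender = gender)
    sc <- data.frame(sample_id = cl$sample_id,
                     risk_score = rep(c(1, -1), each = n / 2))
    class(sc) <- c("risk_scores", "data.frame")
    suppressWarnings(association_suite(stratify(sc, 0), cl,
                                       categorical = "gender"))
  }
  # balanced 2x2 table [[10,10],[10,10]]: statistic 0, p = 1
  bal <- mk(rep(c("F", "M", "F", "M"), each = 10))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  # [[20,5],[5,20]]: E = 12.5 everywhere, X2 = 4 * 7.5^2 / 12.5 = 18
  skew <- mk(c(rep("F", 20), rep("M", 5), rep("F", 5), rep("M", 20)))
  expect_equal(skew$statistic, 18)
  # invariance to category relabelling (row/column permutation)
  swap <- mk(c(rep("M", 20), rep("F", 5), rep("M", 5), rep("F", 20)))
  expect_equal(swap$statistic, 18)
})

test_that("association_suite runs chi-square and staged rank-sum splits", {
  co <- generate_cohort(simulation_config(n_samples = 400, n_marker_genes = 3,
                                          n_background_genes = 0,
                                          censor_rate = 0.2, seed = 55))
  scores <- data.frame(sample_id = co$clinical$sample_id,
                       risk_score = rnorm(400))
  class(scores) <- c("risk_scores", "data.frame")
  scores <- stratify(scores, 0)
  res <- suppressWarnings(association_suite(scores, co$clinical))
  expect_true(all(c("chi-square", "wilcoxon") %in% res$test))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(any(grepl("stage:III-IV_vs_I-II", res$variable)))
  # unstratified scores are rejected
  expect_error(association_suite(scores[, 1:2], co$clinical),
               class = "pairsig_input_error")
})

test_that("Wilcoxon p on 3 vs 3 matches the exact permutation null", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  wt <- wilcox.test(x, y)
  expect_equal(wt$p.value, brute_wilcox_p(x, y))  # = 2/20
  expect_equal(brute_wilcox_p(x, y), 0.1)
  # a non-extreme arrangement also agrees
  x2 <- c(1, 4, 5); y2 <- c(2, 3, 6)
  expect_equal(wilcox.test(x2, y2)$p.value, brute_wilcox_p(x2, y2))
})

test_that("correlation_test covers linear, monotone and tied cases", {
  x <- 1:20
  lin <- correlation_test(x, 2 * x + 1, "pearson")
  expect_equal(lin$statistic, 1)
  mono <- correlation_test(x, exp(x / 3), "spearman")
  expect_equal(mono$statistic, 1)
  expect_lt(correlation_test(x, exp(x / 3), "pearson")$statistic, 1)
  # tied values: rho equals the Pearson correlation of mid-ranks
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  rho <- correlation_test(xt, yt, "spearman")$statistic
  expect_equal(rho, unname(cor(rank(xt), rank(yt))))
  expect_warning(out <- correlation_test(rep(1, 5), 1:5), "zero-variance")
  expect_true(is.na(out$statistic))
  expect_error(correlation_test(1:2, 1:2), class = "pairsig_input_error")
})

test_that("TMB is mutations per megabase", {
  expect_equal(unname(tmb(c(a = 380, b = 0, c = 19))),
               c(10, 0, 0.5))
  expect_equal(unname(tmb(c(a = 100), exome_megabases = 50)), 2)
  expect_error(tmb(c(a = -1)), class = "pairsig_input_error")
  expect_error(tmb(c(a = 1), exome_megabases = 0),
               class = "pairsig_input_error")
})
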