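test_that("km_estimate reproduces product-limit closed forms", {
  # 5 subjects, 1 death at t = 10 with no prior censoring: S(10) = 4/5
  km <- km_estimate(c(10, 20, 30, 40, 50), c(1, 0, 0, 0, 0))
  expect_equal(km$sfun(10), 4 / 5)
  expect_equal(km$sfun(9.99), 1)
  # 3 deaths at distinct times, n = 3: steps 2/3, 1/3, 0
  km3 <- km_estimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km3$surv, c(2 / 3, 1 / 3, 0))
  # no events: S identically 1, with a warning
  expect_warning(km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0)), "no events")
  expect_equal(km0$sfun(c(0, 10)), c(1, 1))
})

test_that("km_estimate is a non-increasing step function within [0, 1]", {
  for (seed in 1:5) {
    d <- toy_surv(50, seed)
    km <- km_estimate(d$time, d$event)
    expect_true(all(diff(km$surv) <= 0))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_equal(km$sfun(0), 1)
  }
})

test_that("logrank_test: identical groups give statistic 0, p = 1", {
  t <- c(5, 10, 15, 20); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p.value, 1)
  expect_error(logrank_test(t, e, rep("a", 4)), class = "pairsig_input_error")
})

test_that("complete group separation is detected as highly significant", {
  # every group-A death precedes any group-B death
  time <- c(1:10, 101:110)
  event <- rep(1, 20)
  grp <- rep(c("A", "B"), each = 10)
  lr <- logrank_test(time, event, grp)
  expect_lt(lr$p.value, 0.01)
  # permutation oracle: observed chi-square should be at the null's extreme
  set.seed(42)
  null_stats <- replicate(2000, {
    g <- sample(grp)
    logrank_test(time, event, g)$statistic
  })
  expect_lt(mean(null_stats >= lr$statistic), 0.01)
})

test_that("log-rank equals the binary-covariate Cox score test (tie-free)", {
  for (seed in 1:5) {
    d <- toy_surv(60, seed + 100)
    if (length(unique(d$x)) < 2) next
    lr <- logrank_test(d$time, d$event, d$x)
    cx <- cox_fit(d$x, d$time, d$event)
    expect_lt(abs(lr$statistic - cx$score_chisq), 1e-6)
    expect_lt(abs(lr$p.value - cx$score_p), 1e-6)
  }
})

test_that("cox_fit matches brute-force partial-likelihood maximization", {
  # 4-subject toy with an interior maximum (the fully ordered variant, with
  # both early deaths in one arm, has a monotone likelihood and is covered
  # by the separation check below)
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(x, time, event)
  brute <- optimize(function(b) brute_breslow_loglik(b, x, time, event),
                    c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(fit$coef[[1]] - brute$maximum), 1e-6)
  expect_lt(abs(fit$loglik[["final"]] - brute$objective), 1e-8)
  # all deaths in one arm first: likelihood increases without bound and the
  # fit must be flagged rather than reported as converged-and-finite
  sep <- cox_fit(c(1, 1, 0, 0), time, event)
  expect_true(sep$flagged)
  # random <= 5-subject instances, including ties
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:5, 1)
    ti <- sample(1:4, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.8)
    xx <- rbinom(n, 1, 0.5)
    if (sum(ev) == 0 || length(unique(xx)) < 2) next
    f <- cox_fit(xx, ti, ev)
    if (!f$converged || f$flagged) next   # separation on tiny n
    b <- optimize(function(b) brute_breslow_loglik(b, xx, ti, ev),
                  c(-15, 15), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(f$coef[[1]] - b$maximum), 1e-6)
  }
})

test_that("cox_fit agrees with survival::coxph (Breslow) on tied data", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 120
  X <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n), c = runif(n))
  time <- sample(1:40, n, replace = TRUE)   # heavy ties
  event <- rbinom(n, 1, 0.7)
  fit <- cox_fit(X, time, event)
  ref <- survival::coxph(survival::Surv(time, event) ~ X,
                         ties = "breslow")
  expect_equal(unname(fit$coef), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik[["final"]], ref$loglik[2], tolerance = 1e-8)
})

test_that("Newton iterations never decrease the log partial likelihood", {
  for (seed in 1:5) {
    set.seed(seed + 30)
    n <- 80
    X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    time <- rexp(n, 1 / (100 * exp(0.8 * X[, 1])))
    event <- rbinom(n, 1, 0.8)
    fit <- cox_fit(X, time, event)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  }
})

test_that("cox_fit null behavior and input guards", {
  set.seed(99)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 1 / 500); event <- rbinom(n, 1, 0.8)
  fit <- cox_fit(x, time, event)
  expect_lt(abs(fit$coef[[1]]), 0.1)
  expect_gt(fit$p[[1]], 0.05)
  expect_error(cox_fit(rep(1, n), time, event), class = "pairsig_input_error")
  expect_error(cox_fit(x, time, rep(0, n)), class = "pairsig_input_error")
})

test_that("univariate_screen keeps order, respects alpha boundaries", {
  co <- generate_cohort(simulation_config(
    n_samples = 300, n_marker_genes = 8, n_background_genes = 0,
    planted_pairs = data.frame(gene_a = "BRG001", gene_b = "BRG002",
                               beta = 1.2),
    expression_location = c(4, 6), censor_rate = 0.2, seed = 17))
  pm <- prevalence_filter(build_pair_matrix(co$expression,
                                            rownames(co$expression)))
  scr <- univariate_screen(pm, co$clinical$os_days, co$clinical$event)
  expect_true("BRG001|BRG002" %in% scr$pm$pairs$pair_id)
  expect_true(all(scr$pm$pairs$pair_id %in% pm$pairs$pair_id))
  # order preserved
  expect_identical(scr$pm$pairs$pair_id,
                   pm$pairs$pair_id[pm$pairs$pair_id %in% scr$pm$pairs$pair_id])
  scr0 <- univariate_screen(pm, co$clinical$os_days, co$clinical$event,
                            alpha = 0)
  expect_equal(nrow(scr0$pm$indicators), 0)
})

test_that("lasso path limits: full shrinkage at large lambda, cox_fit at 0", {
  co <- generate_cohort(simulation_config(
    n_samples = 250, n_marker_genes = 4, n_background_genes = 0,
    planted_pairs = data.frame(gene_a = "BRG001", gene_b = "BRG002",
                               beta = 0.8),
    expression_location = c(4, 6), censor_rate = 0.2, seed = 23))
  pm <- prevalence_filter(build_pair_matrix(co$expression,
                                            rownames(co$expression)),
                          0.05, 0.95)
  path <- lasso_cox_path(pm, co$clinical$os_days, co$clinical$event,
                         lambda = c(10, 1, 0.1, 0.01, 0))
  expect_equal(unname(path$n_active[1]), 0)           # lambda -> infinity
  ref <- cox_fit(t(pm$indicators), co$clinical$os_days, co$clinical$event)
  expect_equal(unname(path$coef[, 5]), unname(ref$coef), tolerance = 1e-4)
  # active-set size non-increasing in lambda along a default path
  dft <- lasso_cox_path(pm, co$clinical$os_days, co$clinical$event)
  expect_true(all(diff(dft$n_active) >= 0))  # lambda decreasing across path
})

test_that("lasso_cox_select is deterministic and guards its preconditions", {
  co <- generate_cohort(simulation_config(
    n_samples = 150, n_marker_genes = 6, n_background_genes = 0,
    planted_pairs = data.frame(gene_a = "BRG001", gene_b = "BRG002",
                               beta = 1.0),
    expression_location = c(4, 6), censor_rate = 0.2, seed = 31))
  pm <- prevalence_filter(build_pair_matrix(co$expression,
                                            rownames(co$expression)),
                          0.05, 0.95)
  a <- lasso_cox_select(pm, co$clinical$os_days, co$clinical$event,
                        n_repetitions = 5, seed = 3)
  b <- lasso_cox_select(pm, co$clinical$os_days, co$clinical$event,
                        n_repetitions = 5, seed = 3)
  expect_identical(a$frequency, b$frequency)
  expect_true(all(a$frequency >= 0 & a$frequency <= 1))
  expect_true(all(a$selected %in% pm$pairs$pair_id))
  expect_error(lasso_cox_select(pm, co$clinical$os_days[1:10],
                                co$clinical$event[1:10], n_repetitions = 2),
               class = "pairsig_input_error")
})
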