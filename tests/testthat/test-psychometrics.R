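# Reliability, outlier rules, OLS + stepwise selection, FDR correlations.

test_that("Cronbach's alpha matches hand computation and boundary cases", {
  # item variances 10/3, 5/3, 5/3; row-sum variance 50/3
  # alpha = 3/2 * (1 - (20/3)/(50/3)) = 0.9
  M <- cbind(c(2, 4, 1, 5), c(1, 3, 2, 4), c(3, 5, 2, 4))
  expect_equal(cronbach_alpha(M), 0.9)

  # duplicated copies of one non-constant item -> exactly 1
  x <- c(1, 5, 2, 8, 3)
  expect_equal(cronbach_alpha(cbind(x, x, x, x)), 1)

  # independent equal-variance items: population alpha 0
  set.seed(42)
  M0 <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_lt(abs(cronbach_alpha(M0)), 0.05)

  expect_error(cronbach_alpha(M[1:2, ]), class = "epelir_structure_error")
  expect_error(cronbach_alpha(M[, 1, drop = FALSE]),
               class = "epelir_structure_error")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), class = "epelir_structure_error")
})

test_that("alpha is invariant to positive scaling and per-item shifts", {
  set.seed(7)
  M <- exchangeable_items(50, 6, 0.4)
  a0 <- cronbach_alpha(M)
  M2 <- sweep(M * 3.7, 2L, rnorm(6, 100, 20), `+`)
  expect_equal(cronbach_alpha(M2), a0, tolerance = 1e-10)
})

test_that("alpha agrees with the Spearman-Brown prediction for exchangeable items", {
  set.seed(11)
  rho <- 0.3; k <- 13L
  truth <- k * rho / (1 + (k - 1) * rho) # 0.8478
  a <- cronbach_alpha(exchangeable_items(5000, k, rho))
  expect_equal(a, truth, tolerance = 0.02)
})

test_that("bootstrap CI behaves: contains the estimate, reproducible, honest width", {
  set.seed(3)
  M <- exchangeable_items(77, 13, 0.3)
  r1 <- bootstrap_alpha_ci(M, n_boot = 500L, seed = 5L)
  r2 <- bootstrap_alpha_ci(M, n_boot = 500L, seed = 5L)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$alpha)
  expect_gte(r1$ci_high, r1$alpha)
  expect_lt(r1$ci_high, 1 + 1e-9)
  expect_error(bootstrap_alpha_ci(M, n_boot = 50L),
               class = "epelir_structure_error")
})

test_that("drop scan isolates a noise item; greedy curve starts at the best drop", {
  set.seed(13)
  M <- exchangeable_items(200, 5, 0.5)
  M <- cbind(M, noise = rnorm(200))
  colnames(M) <- paste0("i", 1:6)
  scan <- alpha_drop_scan(M)
  expect_equal(names(which.max(scan)), "i6") # dropping the noise item helps most

  curve <- alpha_reduced_sets(M, k_min = 2L)
  expect_equal(curve$dropped[2L], "i6")
  expect_equal(curve$alpha[2L], max(scan))
  expect_equal(curve$k, c(6L, 5L, 4L, 3L, 2L))

  # identical items: flat curve at 1
  x <- c(1, 4, 2, 6, 3)
  curve1 <- alpha_reduced_sets(cbind(x, x, x, x), k_min = 2L)
  expect_equal(curve1$alpha, rep(1, 3), tolerance = 1e-12)
})

test_that("univariate outlier rule matches the hand example and the normal rate", {
  # ten zeros and one 10: sample sd = 3.0151, z of the 10 is 3.0151 > 3
  x <- c(rep(0, 10), 10)
  fl <- flag_univariate_outliers(x)
  expect_equal(fl$index, 11L)
  expect_equal(fl$z, 3.0151, tolerance = 1e-4)

  expect_equal(nrow(flag_univariate_outliers(rep(5, 20))), 0L)

  set.seed(29)
  rate <- nrow(flag_univariate_outliers(rnorm(10000))) / 10000
  expect_gte(rate, 0.001)
  expect_lte(rate, 0.006)
})

test_that("Mahalanobis screening: 1-D reduction, whitened data, affine invariance", {
  set.seed(31)
  # one dimension reduces to the squared z against the chi-squared(1) tail
  x <- c(rnorm(50), 6)
  fl <- flag_multivariate_outliers(matrix(x, ncol = 1L), p_threshold = 0.001)
  z2 <- ((x - mean(x)) / sd(x))^2
  expect_equal(fl$index, which(pchisq(z2, 1, lower.tail = FALSE) < 0.001))

  # hand-whitened toy data: D^2 equals squared Euclidean distance
  X <- matrix(rnorm(300 * 3), 300, 3)
  Xw <- scale(X, center = TRUE, scale = FALSE)
  Xw <- Xw %*% solve(chol(cov(Xw)))
  d2 <- mahalanobis(Xw, colMeans(Xw), cov(Xw))
  eu <- rowSums(scale(Xw, center = TRUE, scale = FALSE)^2)
  expect_equal(d2, eu, tolerance = 1e-8, ignore_attr = TRUE)

  # invariance under a nonsingular linear transform of the columns
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 3), 3, 3)
  b <- c(10, -5, 2)
  Y <- sweep(X %*% A, 2L, b, `+`)
  d2x <- mahalanobis(X, colMeans(X), cov(X))
  d2y <- mahalanobis(Y, colMeans(Y), cov(Y))
  expect_lt(max(abs(d2x - d2y)), 1e-8)

  expect_error(flag_multivariate_outliers(X[1:2, ]),
               class = "epelir_structure_error")
})

test_that("two-stage screen catches an injected extreme participant", {
  spec <- default_task_spec()
  model <- default_population_model()
  res <- simulate_and_score_cohort(model, 40L, 101L, spec)
  sess <- res$session_scores
  j <- 7L
  sess$total_actions[j] <- mean(sess$total_actions) +
    10 * sd(sess$total_actions)
  rep_ <- screen_outliers(sess)
  expect_true(sess$participant_id[j] %in% rep_$excluded)
  expect_true(all(abs(rep_$univariate$z) > 3))
})

test_that("OLS fit matches the normal equations, and AIC matches its formula", {
  set.seed(37)
  # noiseless line (summary.lm warns about the perfect fit; that is the point)
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  f <- suppressWarnings(fit_ols(d, "y", "x"))
  expect_equal(f$coefficients$estimate[2L], 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # intercept-only model estimates the mean
  f0 <- fit_ols(d, "y", character())
  expect_equal(f0$coefficients$estimate, mean(d$y))

  # random 30 x 3 problem vs an explicit normal-equations solve
  n <- 30L
  X <- cbind(1, matrix(rnorm(n * 3L), n, 3L))
  beta <- c(1, -2, 0.5, 3)
  y <- X %*% beta + rnorm(n, 0, 0.7)
  d <- data.frame(y = as.vector(y), x1 = X[, 2L], x2 = X[, 3L], x3 = X[, 4L])
  f <- fit_ols(d, "y", c("x1", "x2", "x3"))
  bhat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$coefficients$estimate, as.vector(bhat), tolerance = 1e-8)

  # Gaussian AIC with constants and the variance parameter counted
  rss <- sum(residuals(f$fit)^2)
  p_coef <- 4L
  aic_manual <- n * log(2 * pi * rss / n) + n + 2 * (p_coef + 1)
  expect_equal(f$aic, aic_manual, tolerance = 1e-10)

  # interaction terms are elementwise products alongside main effects
  d$z <- d$x1 * d$x2
  f_int <- fit_ols(d, "y", c("x1", "x2", "x1:x2"))
  f_man <- fit_ols(d, "y", c("x1", "x2", "z"))
  expect_equal(f_int$coefficients$estimate, f_man$coefficients$estimate,
               tolerance = 1e-10)

  expect_error(fit_ols(within(d, dup <- x1), "y", c("x1", "dup")),
               class = "epelir_structure_error")
})

test_that("stepwise selection agrees with exhaustive enumeration and stats::step", {
  set.seed(41)
  n <- 50L
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 * d$x1 + rnorm(n, 0, 0.3)

  exhaustive_best <- function(d, dv, cands) {
    subsets <- unlist(lapply(0:length(cands), combn, x = cands,
                             simplify = FALSE), recursive = FALSE)
    aics <- vapply(subsets, function(s) AIC(epelir:::fit_lm_terms(d, dv, s)), 0)
    sort(subsets[[which.min(aics)]])
  }

  for (dir in c("forward", "backward", "combination")) {
    sel <- stepwise_select(d, "y", c("x1", "x2"), dir)
    expect_equal(sel$final_terms, "x1", label = dir)
    expect_equal(sel$final_terms, exhaustive_best(d, "y", c("x1", "x2")),
                 label = dir)
    expect_lte(sel$final_aic, sel$start_aic)
    if (nrow(sel$steps) > 1L) expect_true(all(diff(sel$steps$aic) < 0))
  }

  # against stats::step on a richer problem
  set.seed(43)
  d2 <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80), e = rnorm(80))
  d2$y <- 1.5 * d2$a - 0.8 * d2$c + rnorm(80)
  fwd <- stepwise_select(d2, "y", c("a", "b", "c", "e"), "forward")
  ref <- step(lm(y ~ 1, d2), scope = y ~ a + b + c + e,
              direction = "forward", trace = 0)
  expect_setequal(fwd$final_terms, attr(terms(ref), "term.labels"))
  bwd <- stepwise_select(d2, "y", c("a", "b", "c", "e"), "backward")
  ref_b <- step(lm(y ~ a + b + c + e, d2), direction = "backward", trace = 0)
  expect_setequal(bwd$final_terms, attr(terms(ref_b), "term.labels"))
})

test_that("the best-of-directions rule prefers lower AIC, then fewer terms", {
  set.seed(47)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- d$x1 + rnorm(40, 0, 0.5)
  paths <- lapply(c("forward", "backward", "combination"),
                  function(dir) stepwise_select(d, "y", c("x1", "x2"), dir))
  best <- pick_best_of_directions(paths)
  expect_equal(best$final_aic, min(vapply(paths, `[[`, 0, "final_aic")))
  # noise-free consistency: all directions agree here
  expect_true(all(vapply(paths, function(p)
    identical(p$final_terms, paths[[1L]]$final_terms), TRUE)))
  expect_error(pick_best_of_directions(list()), class = "epelir_structure_error")
})

test_that("correlation table: self-correlation, BH step-up, monotonicity", {
  set.seed(53)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  d$a2 <- d$a
  tab <- corr_fdr(d, c("a", "b", "c"), c("a2", "b", "c"))
  expect_equal(tab$r[tab$x == "a" & tab$y == "a2"], 1, tolerance = 1e-12)
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_fdr <= 1))

  # independent step-up implementation of the BH adjustment
  m <- nrow(tab)
  o <- order(tab$p_raw)
  adj <- tab$p_raw[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  expect_equal(tab$p_fdr[o], adj, tolerance = 1e-12)

  expect_error(corr_fdr(data.frame(a = rep(1, 10), b = rnorm(10)), "a", "b"),
               class = "epelir_structure_error")
})

test_that("item matrices pivot scenario scores and log dropped participants", {
  spec <- default_task_spec()
  res <- simulate_and_score_cohort(default_population_model(), 12L, 61L, spec)
  M <- item_matrix(res$scenario_scores, "total_score")
  expect_equal(dim(M), c(12L, 13L))
  expect_equal(sum(M), sum(res$session_scores$total_score))
  # inject an undefined efficacy cell and check listwise handling
  scen <- res$scenario_scores
  scen$task_efficacy[scen$participant_id == scen$participant_id[1L]][3L] <- NA
  M2 <- item_matrix(scen, "task_efficacy")
  expect_equal(nrow(M2), 11L)
  expect_equal(attr(M2, "n_dropped"), 1L)
})
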