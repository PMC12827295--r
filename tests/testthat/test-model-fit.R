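test_that("unit scaling maps to [0,1] and keeps its factors", {
  sc <- scale_unit(c(0, 5, 10))
  expect_equal(sc$scaled, c(0, 0.5, 1))
  expect_equal(sc$min, 0); expect_equal(sc$range, 10)
  expect_error(scale_unit(rep(3, 5)), "constant")
  set.seed(2)
  x <- rnorm(40)
  expect_equal(scale_unit(x)$scaled, (x - min(x)) / (max(x) - min(x)))
})

test_that("univariate screening uses Fisher for binaries and t for continuous", {
  # [[5,0],[0,5]]: exact hypergeometric two-sided p = 2/252
  x <- rep(c(0, 1), each = 5)
  cls <- rep(c(FALSE, TRUE), each = 5)
  u <- univariate_confirm(x, cls)
  expect_identical(u$test, "fisher")
  expect_equal(u$p_value, 2 / choose(10, 5) * choose(5, 5) * choose(5, 0),
               tolerance = 1e-10)
  expect_equal(u$p_value, 0.007936508, tolerance = 1e-6)
  expect_true(u$pass)

  u2 <- univariate_confirm(c(0, 0, 1, 1, 0, 0, 1, 1),
                           c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(u2$p_value, 1)   # [[2,2],[2,2]] has no association
  expect_false(u2$pass)

  y <- c(1, 2, 3, 1, 2, 3)
  u3 <- univariate_confirm(y, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(u3$test, "t")
  expect_equal(u3$p_value, 1)   # identical means and variances
  expect_false(u3$pass)
})

test_that("logistic OVR recovers a known weight and survives separation", {
  set.seed(33)
  n <- 2000
  x <- rnorm(n)
  eta <- 0.5 + 1.5 * x
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_logistic_ovr(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_equal(unname(fit$weights[["x"]]), 1.5, tolerance = 0.15)  # within 10%

  # balanced symmetric data -> intercept ~ 0
  xs <- c(-2, -1, 1, 2, -2, -1, 1, 2)
  ys <- c(0, 0, 1, 1, 0, 0, 1, 1)
  fs <- fit_logistic_ovr(matrix(xs, ncol = 1, dimnames = list(NULL, "x")), ys)
  expect_equal(fs$intercept, 0, tolerance = 1e-6)

  # perfectly separated -> ridge fallback keeps weights finite
  sep <- fit_logistic_ovr(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                                 dimnames = list(NULL, "x")),
                          c(0, 0, 0, 1, 1, 1))
  expect_identical(sep$method, "ridge")
  expect_true(all(is.finite(c(sep$weights, sep$intercept))))
})

test_that("rank AUC matches the all-pairs oracle, including ties", {
  expect_equal(roc_auc(1:10, rep(c(FALSE, TRUE), each = 5)), 1)
  expect_equal(roc_auc(10:1, rep(c(FALSE, TRUE), each = 5)), 0)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "one class")
  set.seed(44)
  for (i in 1:10) {
    s <- sample(1:6, 30, replace = TRUE)   # heavy ties
    y <- rbinom(30, 1, 0.4)
    if (sum(y) %in% c(0, 30)) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
})

test_that("identity resampling reduces the bootstrap to a single in-sample fit", {
  co <- make_logit_cohort(80, seed = 5)
  feats <- c("fd", "flair_li")
  bf <- bootstrap_evaluate(co, feats, n_boot = 1, seed = 1,
                           resample_fn = function(b, n) seq_len(n))
  sc <- fracvox:::scale_cohort(co, feats)
  for (k in sort(unique(co$class))) {
    direct <- fit_logistic_ovr(sc$X, as.numeric(co$class == k))
    expect_equal(unname(bf$mean_weights[k, ]), unname(direct$weights),
                 tolerance = 1e-10)
  }
  # identity resample leaves no out-of-bootstrap patients: AUC is NA, logged
  expect_true(all(is.na(bf$auc_replicates)))
  expect_true(length(bf$skipped) >= 1)
})

test_that("a perfectly separating feature yields out-of-bootstrap AUC 1", {
  set.seed(6)
  n <- 60
  co <- data.frame(x = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),
                   noise = rnorm(n),
                   class = rep(c("a", "b"), each = n / 2))
  bf <- bootstrap_evaluate(co, "x", n_boot = 30, seed = 2)
  expect_equal(unname(bf$auc_mean[["mean"]]), 1, tolerance = 1e-12)
})

test_that("bootstrap evaluation is bit-reproducible under a fixed seed", {
  co <- make_logit_cohort(100, seed = 7)
  a <- bootstrap_evaluate(co, c("fd", "cystic"), n_boot = 20, seed = 9)
  b <- bootstrap_evaluate(co, c("fd", "cystic"), n_boot = 20, seed = 9)
  expect_identical(a$mean_weights, b$mean_weights)
  expect_identical(a$auc_replicates, b$auc_replicates)
})

test_that("greedy exhaustive selection prefers dominant and smaller subsets", {
  set.seed(10)
  n <- 80
  co <- data.frame(
    strong = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),   # AUC ~ 1 alone
    weak = rnorm(n),
    class = rep(c("a", "b"), each = n / 2))
  sel <- greedy_exhaustive_select(co, fractal_candidates = c("strong", "weak"),
                                  n_boot = 15, seed = 3)
  expect_identical(sel$fractal, "strong")   # weak fails screen or adds nothing

  # pure-noise candidates cannot pass the p < 0.05 screen
  co2 <- data.frame(n1 = rnorm(n), n2 = rnorm(n),
                    class = rep(c("a", "b"), each = n / 2))
  expect_error(greedy_exhaustive_select(co2, c("n1", "n2"), n_boot = 5, seed = 3),
               "screen")
})

test_that("ties between nested feature sets go to the smaller set", {
  # two copies of the same perfect predictor: {A} and {A,B} tie at AUC 1
  set.seed(12)
  n <- 60
  x <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  co <- data.frame(a_copy = x, b_copy = x,
                   class = rep(c("a", "b"), each = n / 2))
  sel <- greedy_exhaustive_select(co, c("a_copy", "b_copy"),
                                  n_boot = 10, seed = 4)
  expect_identical(sel$fractal, "a_copy")
})

test_that("absorbing the scaling factors reproduces scaled-form scores exactly", {
  expect_equal(absorb_scaling(c(f = 2), 1.5,
                              list(f = list(min = 0, range = 2)))$weights[["f"]], 1)
  m <- absorb_scaling(c(f = 1), 0, list(f = list(min = 5, range = 10)))
  expect_equal(m$weights[["f"]], 0.1)
  expect_equal(m$threshold, 0.5)   # intercept shifted by -0.5, negated

  set.seed(14)
  for (i in 1:5) {
    w <- c(u = rnorm(1), v = rnorm(1), w = rnorm(1))
    b0 <- rnorm(1)
    factors <- list(u = list(min = rnorm(1), range = runif(1, 0.5, 4)),
                    v = list(min = rnorm(1), range = runif(1, 0.5, 4)),
                    w = list(min = 0, range = 1))
    m <- absorb_scaling(w, b0, factors)
    X <- cbind(u = rnorm(100), v = rnorm(100), w = rbinom(100, 1, 0.5))
    scaled_scores <- apply(X, 1, function(x) {
      xs <- vapply(names(w), function(f)
        (x[[f]] - factors[[f]]$min) / factors[[f]]$range, numeric(1))
      sum(w * xs) + b0
    })
    raw_scores <- apply(X, 1, function(x)
      class_score(x, m) - m$threshold)
    expect_equal(raw_scores, scaled_scores, tolerance = 1e-10)
  }
})

test_that("the full pipeline recovers generating weight signs and truth-level AUC", {
  co <- make_logit_cohort(300, seed = 11)
  bf <- bootstrap_evaluate(co, c("fd", "flair_li", "cystic", "volume_cm3"),
                           n_boot = 100, seed = 42)
  gen <- default_generating_models()
  for (k in names(gen))
    expect_equal(unname(sign(bf$mean_weights[k, names(gen[[k]]$weights)])),
                 unname(sign(gen[[k]]$weights)), info = k)
  tru <- true_model_auc(n_sim = 2e4, seed = 17)
  expect_lt(abs(bf$auc_mean[["mean"]] - tru[["mean"]]), 0.05)
})

test_that("fit_scoring_system returns a usable classed model object", {
  co <- make_cohort(seed = 8)
  fit <- fit_scoring_system(co, c("fd", "flair_li"), c("volume_cm3", "cystic"),
                            n_boot = 20, seed = 5)
  expect_s3_class(fit, "scoring_fit")
  expect_true(all(rownames(coef(fit)) == fit$class_levels))
  pred <- predict(fit, co[1:5, ])
  expect_equal(nrow(pred), 5)
  expect_true(all(pred$predicted %in% c(fit$class_levels, "none")))
  expect_output(print(fit), "scoring_fit")
  expect_output(summary(fit), "out-of-bootstrap")
})
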