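published_ors <- list(
  other = c(fd = 2.855, flair_li = 2.179, cystic = 1.639, volume_cm3 = 0.984),
  medulloblastoma = c(fd = 3.896, flair_li = 0.321, cystic = 0.264,
                      volume_cm3 = 1.003),
  pilocytic_astrocytoma = c(fd = 0.110, flair_li = 1.266, cystic = 2.214,
                            volume_cm3 = 1.010)
)

test_that("every published odds ratio is exp(weight) to 3 decimals", {
  models <- published_model()
  for (k in names(published_ors)) {
    for (f in names(published_ors[[k]])) {
      expect_equal(odds_ratio(models[[k]]$weights[[f]]),
                   published_ors[[k]][[f]],
                   info = sprintf("%s / %s", k, f))
    }
  }
  expect_equal(odds_ratio(0), 1)
})

test_that("the worked scoring example reproduces the hand-computed totals", {
  f <- c(fd = 2.0, flair_li = 1.0, cystic = 1, volume_cm3 = 30)
  models <- published_model()
  expect_equal(class_score(f, models$other), 2.891, tolerance = 1e-12)
  expect_equal(class_score(f, models$medulloblastoma), 0.344, tolerance = 1e-12)
  expect_equal(class_score(f, models$pilocytic_astrocytoma), -3.079,
               tolerance = 1e-12)

  r <- predict_class(f)
  expect_equal(unname(r$exceeds),
               c(FALSE, FALSE, TRUE))
  expect_equal(unname(r$deltas[["pilocytic_astrocytoma"]]), 2.603,
               tolerance = 1e-12)
  expect_identical(r$predicted, "pilocytic_astrocytoma")

  zero <- c(fd = 0, flair_li = 0, cystic = 0, volume_cm3 = 0)
  expect_true(all(vapply(models, function(m) class_score(zero, m),
                         numeric(1)) == 0))
})

test_that("the largest delta wins when several classes exceed their thresholds", {
  f <- c(fd = 3.0, flair_li = 0.0, cystic = 1, volume_cm3 = 100)
  r <- predict_class(f)
  expect_equal(sum(r$exceeds), 2)
  expect_equal(unname(r$deltas[["medulloblastoma"]]), 0.602, tolerance = 1e-12)
  expect_equal(unname(r$deltas[["pilocytic_astrocytoma"]]), 0.862,
               tolerance = 1e-12)
  expect_identical(r$predicted, "pilocytic_astrocytoma")
})

test_that("the system abstains when no class exceeds its threshold", {
  hi <- lapply(published_model(), function(m) {
    m$threshold <- Inf; m
  })
  r <- predict_class(c(fd = 2, flair_li = 1, cystic = 1, volume_cm3 = 30), hi)
  expect_identical(r$predicted, "none")
  expect_false(any(r$exceeds))
})

test_that("scores at exactly the threshold do not qualify (strict inequality)", {
  m <- class_model("x", c(fd = 1), threshold = 2)
  r <- predict_class(c(fd = 2), list(m))
  expect_identical(r$predicted, "none")
  r2 <- predict_class(c(fd = 2 + 1e-9), list(m))
  expect_identical(r2$predicted, "x")
})

test_that("the decision is invariant to a common shift of totals and thresholds", {
  set.seed(21)
  for (i in 1:25) {
    f <- c(fd = runif(1, 1, 3), flair_li = runif(1, -1, 2),
           cystic = rbinom(1, 1, 0.5), volume_cm3 = runif(1, 3, 110))
    base <- predict_class(f)
    shift <- runif(1, -5, 5)
    shifted <- lapply(published_model(), function(m) {
      m$weights <- m$weights; m$threshold <- m$threshold + shift
      m
    })
    # shifting thresholds and totals together: emulate by also shifting totals
    r2 <- predict_class(f, shifted)
    expect_equal(unname(base$deltas - (r2$deltas + shift)), rep(0, 3),
                 tolerance = 1e-12)
    # decision totality: exactly one outcome, always defined
    expect_true(base$predicted %in% c(names(base$totals), "none"))
  }
})

test_that("exact delta ties fall back to the fixed class order", {
  ms <- list(a = class_model("a", c(x = 1), 0), b = class_model("b", c(x = 1), 0))
  r <- predict_class(c(x = 1), ms)
  expect_identical(r$predicted, "a")
})
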