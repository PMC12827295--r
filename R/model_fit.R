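# The procedure that produces a scoring system from a cohort table:
# univariate screening, 0-1 scaling, one-vs-rest logistic regression under
# bootstrap resampling (n = 100 with replacement), greedy exhaustive feature
# selection on out-of-bootstrap AUC (fractal stage first, then clinical),
# weight averaging across replicates, and absorption of the scaling factors
# back into raw-unit weights with per-class thresholds.

#' Scale a feature to the unit interval
#'
#' @param x numeric vector with positive range.
#' @return List: `scaled` = (x - min) / (max - min), plus the retained `min`
#'   and `range` factors needed to absorb the scaling later.
#' @export
scale_unit <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop("feature contains non-finite values")
  if (diff(r) == 0) stop("feature is constant; unit scaling is degenerate")
  list(scaled = (x - r[1]) / diff(r), min = r[1], range = diff(r))
}

is_binary <- function(x) all(x %in% c(0, 1))

#' Univariate screening of one feature against one class
#'
#' Binary features are tested with a two-sided Fisher's exact test of the
#' 2x2 feature-by-class table; continuous features with an independent
#' samples t-test (pooled variance). The gate passes at p < 0.05.
#'
#' @param x feature values.
#' @param in_class logical, class membership (class vs rest).
#' @param alpha significance gate, default 0.05.
#' @return List: `p_value`, `pass`, `test` ("fisher" or "t").
#' @export
univariate_confirm <- function(x, in_class, alpha = 0.05) {
  in_class <- as.logical(in_class)
  if (!any(in_class) || all(in_class)) stop("both class groups must be non-empty")
  if (is_binary(x)) {
    tab <- table(factor(x, levels = c(0, 1)),
                 factor(in_class, levels = c(FALSE, TRUE)))
    p <- fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    a <- x[in_class]; b <- x[!in_class]
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- t.test(a, b, var.equal = TRUE)$p.value
    }
    test <- "t"
  }
  list(p_value = p, pass = p < alpha, test = test)
}

#' One-vs-rest logistic fit
#'
#' Unpenalized maximum-likelihood binary logistic regression; if the fit
#' fails to converge or separates (fitted probabilities pinned to 0/1), the
#' model is refit by IRLS with a tiny ridge penalty (1e-6) on the slopes,
#' which keeps weights finite without materially biasing them.
#'
#' @param X numeric matrix of (scaled) features, one column per feature.
#' @param y logical or 0/1 outcome (class vs rest).
#' @param ridge fallback penalty, default 1e-6.
#' @param tol IRLS convergence tolerance, default 1e-8.
#' @return List: named `weights`, `intercept`, `method` ("ml" or "ridge").
#' @export
fit_logistic_ovr <- function(X, y, ridge = 1e-6, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (sum(y) < 3) stop("class has fewer than 3 members in the sample")
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial(),
            control = list(epsilon = tol, maxit = 100)))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10) ||
    any(!is.finite(fit$coefficients))
  if (!separated) {
    co <- fit$coefficients
    return(list(weights = co[-1], intercept = unname(co[1]), method = "ml"))
  }
  co <- ridge_logistic_irls(cbind(1, X), y, ridge = ridge, tol = tol)
  if (is.null(co)) stop("logistic fit failed to converge even with ridge fallback")
  w <- unname(co[-1]); names(w) <- colnames(X)
  list(weights = w, intercept = unname(co[1]), method = "ridge")
}

# IRLS for logistic regression with an L2 penalty on all but the intercept.
ridge_logistic_irls <- function(Z, y, ridge, tol, maxit = 200) {
  p <- ncol(Z)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Z, Z * w) + pen
    g <- crossprod(Z, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) return(beta)
  }
  beta   # converged enough for a bounded-penalty fit
}

#' Rank-based ROC AUC
#'
#' Tie-corrected Mann-Whitney estimator: ties contribute one half.
#'
#' @param scores numeric predictor.
#' @param labels logical or 0/1 outcome; both values must be present.
#' @return The area under the ROC curve.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- as.numeric(sum(y)); n0 <- as.numeric(sum(!y))
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

scale_cohort <- function(cohort, features) {
  X <- matrix(NA_real_, nrow(cohort), length(features),
              dimnames = list(NULL, features))
  factors <- list()
  for (f in features) {
    x <- cohort[[f]]
    if (is_binary(x)) {
      X[, f] <- x
      factors[[f]] <- list(min = 0, range = 1)
    } else {
      sc <- scale_unit(x)
      X[, f] <- sc$scaled
      factors[[f]] <- list(min = sc$min, range = sc$range)
    }
  }
  list(X = X, factors = factors)
}

#' Bootstrapped one-vs-rest evaluation of a feature set
#'
#' Continuous features are scaled to 0-1 on the full cohort. For each of
#' `n_boot` replicates the cohort is resampled with replacement; one logistic
#' model per class is fit on the resample and evaluated on the
#' out-of-bootstrap patients (those never drawn): per-class ROC AUC of the
#' class score, plus macro accuracy / precision / recall of the
#' threshold-and-largest-delta classifier (per-replicate thresholds
#' `-intercept`, i.e. the 0.5-probability rule; abstentions count as
#' incorrect). Weights are averaged across replicates; replicates whose
#' out-of-bootstrap set is empty or one-class, or where a class is too rare
#' to fit, are skipped and logged.
#'
#' @param cohort data frame with a `class` column and feature columns.
#' @param features character vector of feature column names.
#' @param n_boot number of bootstrap replicates, default 100.
#' @param seed RNG seed; fixed seed gives a bit-identical result.
#' @param resample_fn optional hook `function(b, n)` returning the index
#'   vector of replicate `b` (testing aid; e.g. identity resampling).
#' @param class_levels class labels; default the sorted unique labels.
#' @return An object of class `boot_fit`: per-class mean weights and
#'   intercepts (scaled space), scaling `factors`, per-class and mean AUC
#'   with 2.5/97.5 percentile CIs, classifier metrics, and a `skipped` log.
#' @export
bootstrap_evaluate <- function(cohort, features, n_boot = 100, seed = 1L,
                               resample_fn = NULL, class_levels = NULL) {
  stopifnot("class" %in% names(cohort), all(features %in% names(cohort)))
  if (is.null(class_levels)) class_levels <- sort(unique(as.character(cohort$class)))
  if (length(class_levels) < 2) stop("need at least 2 classes")
  n <- nrow(cohort)
  sc <- scale_cohort(cohort, features)
  X <- sc$X
  lab <- as.character(cohort$class)

  set.seed(seed)
  draws <- lapply(seq_len(n_boot), function(b)
    if (is.null(resample_fn)) sample.int(n, n, replace = TRUE)
    else resample_fn(b, n))

  K <- length(class_levels)
  wsum <- matrix(0, K, length(features), dimnames = list(class_levels, features))
  isum <- setNames(numeric(K), class_levels)
  wcount <- setNames(numeric(K), class_levels)
  auc <- matrix(NA_real_, n_boot, K, dimnames = list(NULL, class_levels))
  acc <- prec <- rec <- rep(NA_real_, n_boot)
  skipped <- list()

  for (b in seq_len(n_boot)) {
    idx <- draws[[b]]
    oob <- setdiff(seq_len(n), unique(idx))
    models <- list()
    ok <- TRUE
    for (k in class_levels) {
      yk <- as.numeric(lab[idx] == k)
      if (sum(yk) < 3 || sum(1 - yk) < 3) {
        skipped[[length(skipped) + 1]] <-
          list(replicate = b, reason = sprintf("class '%s' too rare in resample", k))
        ok <- FALSE; break
      }
      fit <- tryCatch(fit_logistic_ovr(X[idx, , drop = FALSE], yk),
                      error = function(e) NULL)
      if (is.null(fit)) {
        skipped[[length(skipped) + 1]] <-
          list(replicate = b, reason = sprintf("fit failed for class '%s'", k))
        ok <- FALSE; break
      }
      models[[k]] <- fit
    }
    if (!ok) next

    for (k in class_levels) {
      wsum[k, ] <- wsum[k, ] + models[[k]]$weights
      isum[k] <- isum[k] + models[[k]]$intercept
      wcount[k] <- wcount[k] + 1
    }
    if (length(oob) == 0) {   # fit kept; nothing to evaluate on
      skipped[[length(skipped) + 1]] <-
        list(replicate = b, reason = "empty out-of-bootstrap set")
      next
    }

    scores <- vapply(class_levels, function(k)
      drop(X[oob, , drop = FALSE] %*% models[[k]]$weights) + models[[k]]$intercept,
      numeric(length(oob)))
    scores <- matrix(scores, nrow = length(oob),
                     dimnames = list(NULL, class_levels))
    for (k in class_levels) {
      yk <- lab[oob] == k
      if (any(yk) && any(!yk)) auc[b, k] <- roc_auc(scores[, k], yk)
    }
    # threshold-and-delta classifier on the out-of-bootstrap patients:
    # score_k > 0 in scaled space is the 0.5-probability rule
    pred <- apply(scores, 1, function(s)
      if (any(s > 0)) class_levels[which.max(s)] else "none")
    acc[b] <- mean(pred == lab[oob])
    pr <- vapply(class_levels, function(k) {
      pk <- pred == k
      if (!any(pk)) return(NA_real_)
      mean(lab[oob][pk] == k)
    }, numeric(1))
    rc <- vapply(class_levels, function(k) {
      tk <- lab[oob] == k
      if (!any(tk)) return(NA_real_)
      mean(pred[tk] == k)
    }, numeric(1))
    prec[b] <- mean(pr, na.rm = TRUE)
    rec[b] <- mean(rc, na.rm = TRUE)
  }

  if (all(wcount == 0)) stop("every bootstrap replicate was skipped")
  ci <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
    setNames(c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE)),
             c("mean", "lo", "hi"))
  }
  mean_auc_rep <- rowMeans(auc)
  structure(list(
    features = features,
    class_levels = class_levels,
    mean_weights = sweep(wsum, 1, pmax(wcount, 1), "/"),
    mean_intercepts = isum / pmax(wcount, 1),
    factors = sc$factors,
    auc_per_class = t(apply(auc, 2, ci)),
    auc_mean = ci(mean_auc_rep),
    accuracy = ci(acc), precision = ci(prec), recall = ci(rec),
    auc_replicates = auc,
    n_boot = n_boot, n_used = wcount, skipped = skipped, seed = seed
  ), class = "boot_fit")
}

#' @export
print.boot_fit <- function(x, ...) {
  cat(sprintf("<boot_fit> features {%s}, %d bootstrap replicates (%d skipped events)\n",
              paste(x$features, collapse = ", "), x$n_boot, length(x$skipped)))
  cat(sprintf("mean out-of-bootstrap AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc_mean[1], x$auc_mean[2], x$auc_mean[3]))
  print(round(x$auc_per_class, 3))
  invisible(x)
}

#' Two-stage greedy exhaustive feature selection
#'
#' Candidates failing the univariate screen (p < 0.05 against every class)
#' are dropped. Stage 1 searches all non-empty subsets of the fractal
#' candidates for the highest mean out-of-bootstrap AUC; stage 2 fixes the
#' stage-1 winners and searches all subsets (including the empty one) of the
#' clinical candidates. Staging the search this way avoids the combinatorial
#' explosion of a joint search. Ties prefer the smaller subset, then
#' lexicographic feature order.
#'
#' @inheritParams bootstrap_evaluate
#' @param fractal_candidates,clinical_candidates feature column names.
#' @param alpha univariate gate, default 0.05.
#' @return List: `selected` (final feature set), `fractal`, `clinical`,
#'   `screened_out`, and the search `trace` (subset, mean AUC per stage).
#' @export
greedy_exhaustive_select <- function(cohort, fractal_candidates,
                                     clinical_candidates = character(),
                                     n_boot = 100, seed = 1L, alpha = 0.05,
                                     class_levels = NULL) {
  if (is.null(class_levels)) class_levels <- sort(unique(as.character(cohort$class)))
  screen <- function(f) {
    any(vapply(class_levels, function(k)
      univariate_confirm(cohort[[f]], cohort$class == k, alpha = alpha)$pass,
      logical(1)))
  }
  keep_f <- fractal_candidates[vapply(fractal_candidates, screen, logical(1))]
  keep_c <- clinical_candidates[vapply(clinical_candidates, screen, logical(1))]
  screened_out <- setdiff(c(fractal_candidates, clinical_candidates),
                          c(keep_f, keep_c))
  if (!length(keep_f))
    stop("no fractal candidate passed the univariate screen (p < 0.05)")

  subset_auc <- function(feats) {
    bf <- bootstrap_evaluate(cohort, feats, n_boot = n_boot, seed = seed,
                             class_levels = class_levels)
    unname(bf$auc_mean[1])
  }
  search_stage <- function(base, pool, allow_empty) {
    sizes <- (if (allow_empty) 0 else 1):length(pool)
    cand <- list(); aucs <- numeric(0)
    for (k in sizes) {
      sets <- if (k == 0) list(character(0)) else
        combn(pool, k, simplify = FALSE)
      for (s in sets) {
        feats <- c(base, sort(s))
        cand[[length(cand) + 1]] <- sort(s)
        aucs <- c(aucs, subset_auc(feats))
      }
    }
    # ties -> smaller subset, then lexicographic order (cand is already
    # enumerated smallest-first, combn emits lexicographic subsets)
    best <- which.max(aucs)
    list(subset = cand[[best]],
         trace = data.frame(subset = vapply(cand, paste, "", collapse = "+"),
                            mean_oob_auc = aucs))
  }
  st1 <- search_stage(character(0), sort(keep_f), allow_empty = FALSE)
  st2 <- if (length(keep_c))
    search_stage(st1$subset, sort(keep_c), allow_empty = TRUE)
  else list(subset = character(0), trace = NULL)
  list(selected = c(st1$subset, st2$subset),
       fractal = st1$subset, clinical = st2$subset,
       screened_out = screened_out,
       trace = list(fractal = st1$trace, clinical = st2$trace))
}

#' Absorb 0-1 scaling factors into raw-unit class models
#'
#' A model fit on scaled features `(x - min) / range` is algebraically
#' identical to a raw-unit model with weights `w / range` and intercept
#' `intercept - sum(w * min / range)`. The class threshold is the negated
#' absorbed intercept, so "total > threshold" is exactly "logit > 0"
#' (probability one half).
#'
#' @param weights named numeric weights in scaled space.
#' @param intercept scaled-space intercept.
#' @param factors named list of `list(min, range)` from [scale_unit()]
#'   (binary features use min 0, range 1).
#' @param class_name label for the resulting [class_model()].
#' @return A [class_model()] in raw units.
#' @export
absorb_scaling <- function(weights, intercept, factors, class_name = "class") {
  stopifnot(all(names(weights) %in% names(factors)))
  raw <- vapply(names(weights), function(f)
    weights[[f]] / factors[[f]]$range, numeric(1))
  shift <- sum(vapply(names(weights), function(f)
    weights[[f]] * factors[[f]]$min / factors[[f]]$range, numeric(1)))
  class_model(class_name, setNames(raw, names(weights)),
              threshold = -(intercept - shift))
}

#' Fit a scoring system from a cohort
#'
#' The full pipeline: univariate screening and two-stage greedy exhaustive
#' feature selection on out-of-bootstrap AUC (optional), bootstrapped
#' one-vs-rest logistic fits with weight averaging, and scale absorption into
#' a raw-unit scoring system of the same form as [published_model()].
#'
#' @inheritParams greedy_exhaustive_select
#' @param select if `FALSE`, skip selection and use all candidates.
#' @return An object of class `scoring_fit`: the selection, the `boot_fit`
#'   evaluation, and `models` (raw-unit [class_model()]s keyed by class).
#' @export
fit_scoring_system <- function(cohort, fractal_candidates,
                               clinical_candidates = character(),
                               n_boot = 100, seed = 1L, alpha = 0.05,
                               select = TRUE, class_levels = NULL) {
  if (is.null(class_levels)) class_levels <- sort(unique(as.character(cohort$class)))
  sel <- if (select)
    greedy_exhaustive_select(cohort, fractal_candidates, clinical_candidates,
                             n_boot = n_boot, seed = seed, alpha = alpha,
                             class_levels = class_levels)
  else list(selected = c(fractal_candidates, clinical_candidates),
            fractal = fractal_candidates, clinical = clinical_candidates,
            screened_out = character(0), trace = NULL)
  bf <- bootstrap_evaluate(cohort, sel$selected, n_boot = n_boot, seed = seed,
                           class_levels = class_levels)
  models <- lapply(class_levels, function(k)
    absorb_scaling(bf$mean_weights[k, ], bf$mean_intercepts[[k]], bf$factors,
                   class_name = k))
  names(models) <- class_levels
  structure(list(selection = sel, boot = bf, models = models,
                 class_levels = class_levels, call = match.call()),
            class = "scoring_fit")
}

#' @export
print.scoring_fit <- function(x, ...) {
  cat("<scoring_fit>\n")
  cat("selected features:", paste(x$selection$selected, collapse = ", "), "\n")
  cat(sprintf("mean out-of-bootstrap AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$boot$auc_mean[1], x$boot$auc_mean[2], x$boot$auc_mean[3]))
  invisible(x)
}

#' @export
summary.scoring_fit <- function(object, ...) {
  x <- object
  cat("Scoring system fit\n")
  cat("==================\n")
  cat("features:", paste(x$selection$selected, collapse = ", "), "\n")
  if (length(x$selection$screened_out))
    cat("screened out (p >= 0.05):",
        paste(x$selection$screened_out, collapse = ", "), "\n")
  cat(sprintf("\nout-of-bootstrap AUC (mean over %d replicates):\n", x$boot$n_boot))
  print(round(x$boot$auc_per_class, 3))
  cat(sprintf("mean AUC %.3f (%.3f-%.3f); accuracy %.3f; precision %.3f; recall %.3f\n",
              x$boot$auc_mean[1], x$boot$auc_mean[2], x$boot$auc_mean[3],
              x$boot$accuracy[1], x$boot$precision[1], x$boot$recall[1]))
  cat("\nraw-unit class models (weights | threshold):\n")
  for (m in x$models)
    cat(sprintf("  %-22s %s | %.3f\n", m$class_name,
                paste(sprintf("%s %.3f", names(m$weights), m$weights),
                      collapse = ", "), m$threshold))
  invisible(x)
}

#' @export
coef.scoring_fit <- function(object, ...) {
  t(vapply(object$models, function(m) c(m$weights, threshold = m$threshold),
           numeric(length(object$models[[1]]$weights) + 1)))
}

#' Predict classes for new patients with a fitted scoring system
#'
#' @param object a `scoring_fit`.
#' @param newdata data frame holding the selected feature columns.
#' @param ... unused.
#' @return Data frame with per-class totals, deltas, and the `predicted`
#'   class (or "none") per row.
#' @export
predict.scoring_fit <- function(object, newdata, ...) {
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    f <- unlist(newdata[i, object$selection$selected, drop = FALSE])
    r <- predict_class(f, object$models)
    c(as.list(setNames(r$totals, paste0("total_", names(r$totals)))),
      as.list(setNames(r$deltas, paste0("delta_", names(r$deltas)))),
      predicted = r$predicted)
  })
  do.call(rbind, lapply(out, as.data.frame))
}
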