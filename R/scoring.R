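# The published three-class histology scoring system for pediatric posterior
# fossa tumors: one linear score per class (other / medulloblastoma /
# pilocytic astrocytoma) in raw feature units, each with its own threshold,
# and a largest-delta decision rule when several thresholds are exceeded.

SCORE_CLASSES <- c("other", "medulloblastoma", "pilocytic_astrocytoma")
SCORE_FEATURES <- c("fd", "flair_li", "cystic", "volume_cm3")

#' One class of a scoring system
#'
#' @param class_name class label.
#' @param weights named numeric weights on the logit scale, in raw feature
#'   units, one per feature of the system.
#' @param threshold score cut-point; a patient belongs to the class when the
#'   total score is strictly greater.
#' @return An object of class `class_model`.
#' @export
class_model <- function(class_name, weights, threshold) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            is.numeric(threshold), length(threshold) == 1)
  structure(list(class_name = class_name, weights = weights,
                 threshold = unname(threshold)),
            class = "class_model")
}

#' The published posterior-fossa scoring system
#'
#' Per-class logit weights and thresholds of the published estimator for
#' {FD, FLAIR LI, cystic component, tumor volume (cm^3)}. Weights are in raw
#' units: the 0-1 scaling used during fitting is already absorbed into them,
#' so features are plugged in as measured (volume in cm^3, cystic as 0/1).
#'
#' @return A named list of three [class_model()]s
#'   (`other`, `medulloblastoma`, `pilocytic_astrocytoma`).
#' @export
published_model <- function() {
  w <- function(fd, li, cy, vol) c(fd = fd, flair_li = li, cystic = cy,
                                   volume_cm3 = vol)
  list(
    other = class_model("other", w(1.049, 0.779, 0.494, -0.016), 4.053),
    medulloblastoma = class_model("medulloblastoma",
                                  w(1.360, -1.136, -1.330, 0.003), 2.448),
    pilocytic_astrocytoma = class_model("pilocytic_astrocytoma",
                                        w(-2.205, 0.236, 0.795, 0.010), -5.682)
  )
}

as_feature_vector <- function(f) {
  if (is.data.frame(f)) {
    stopifnot(nrow(f) == 1)
    f <- unlist(f[intersect(names(f), SCORE_FEATURES)])
  }
  if (is.list(f)) f <- unlist(f)
  stopifnot(is.numeric(f), !is.null(names(f)))
  f
}

#' Total score of a patient under one class model
#'
#' Multiplies each weight by the raw parameter value and sums.
#'
#' @param features named numeric vector (or one-row data frame) holding the
#'   model's features in raw units.
#' @param model a [class_model()].
#' @return The total score (logit scale).
#' @export
class_score <- function(features, model) {
  f <- as_feature_vector(features)
  miss <- setdiff(names(model$weights), names(f))
  if (length(miss))
    stop("missing features: ", paste(miss, collapse = ", "))
  sum(model$weights * f[names(model$weights)])
}

#' Classify a patient with a scoring system
#'
#' Computes every class total; a class is eligible when its total strictly
#' exceeds its threshold. With several eligible classes the one with the
#' largest delta (total minus threshold) wins; exact delta ties fall back to
#' the fixed class order of `models`. With no eligible class the system
#' abstains (`predicted = "none"`).
#'
#' @inheritParams class_score
#' @param models a list of [class_model()]s, default [published_model()].
#' @return An object of class `scoring_result`: `totals`, `thresholds`,
#'   `exceeds`, `deltas` and `predicted`.
#' @export
predict_class <- function(features, models = published_model()) {
  totals <- vapply(models, function(m) class_score(features, m), numeric(1))
  thresholds <- vapply(models, `[[`, numeric(1), "threshold")
  nm <- vapply(models, `[[`, character(1), "class_name")
  names(totals) <- names(thresholds) <- nm
  deltas <- totals - thresholds
  exceeds <- totals > thresholds
  predicted <- if (any(exceeds)) {
    elig <- which(exceeds)
    unname(nm[elig[which.max(deltas[elig])]])  # which.max keeps the first on ties
  } else "none"
  structure(list(totals = totals, thresholds = thresholds, exceeds = exceeds,
                 deltas = deltas, predicted = predicted),
            class = "scoring_result")
}

#' @export
print.scoring_result <- function(x, ...) {
  cat("<scoring_result>\n")
  df <- data.frame(total = x$totals, threshold = x$thresholds,
                   delta = x$deltas, exceeds = x$exceeds)
  print(round(df, 3))
  cat("predicted:", x$predicted, "\n")
  invisible(x)
}

#' Odds ratio of a logit weight
#'
#' @param weight regression coefficient on the logit scale.
#' @param digits rounding for display (the conventional 3 decimals).
#' @return `exp(weight)`, rounded to `digits`.
#' @export
odds_ratio <- function(weight, digits = 3) {
  round(exp(weight), digits)
}
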