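#' Specification of a progression classifier
#'
#' @param predictors subset of \code{c("dcv", "dfv", "scv", "sfv")} (the
#'   LSC-corrected deltas and the regional subtraction volumes).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param fold_seed RNG seed for the fold assignment.
#' @param grouping \code{"patient"} (all follow-ups of a patient share a
#'   fold, preventing random-effect leakage) or \code{"observation"}.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(predictors = c("dcv", "dfv", "scv", "sfv"),
                       n_folds = 5L, fold_seed = 1L,
                       grouping = c("patient", "observation")) {
  grouping <- match.arg(grouping)
  stopifnot(length(predictors) >= 1,
            all(predictors %in% c("dcv", "dfv", "scv", "sfv")),
            n_folds >= 2)
  structure(list(predictors = predictors, n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed), grouping = grouping),
            class = "model_spec")
}

.model_frame <- function(records, predictors) {
  need <- c("patient_id", "progression", predictors)
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  d <- records[, need]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$patient_id <- factor(d$patient_id)
  d
}

#' Fit the logistic mixed-effects progression model
#'
#' Logistic regression of the binary progression endpoint on the volumetric
#' determinants with a per-patient random intercept (Laplace approximation
#' via \code{lme4::glmer}). Reported P-values are two-sided Wald tests,
#' matching the estimate / standard error / P layout of the model table.
#'
#' @param records labeled change records (rows with NA progression are
#'   excluded).
#' @param spec a \code{\link{model_spec}}.
#' @return list of class \code{glmm_fit}: \code{model} (merMod),
#'   \code{coefficients} (data.frame: estimate, std_error, p_value),
#'   \code{ranef_sd} (random-intercept SD), \code{converged},
#'   \code{n_obs}, \code{n_patients}.
#' @export
fit_glmm <- function(records, spec = model_spec()) {
  d <- .model_frame(records, spec$predictors)
  if (nlevels(d$patient_id) < 2) stop("need at least 2 patients")
  if (length(unique(d$progression)) < 2)
    stop("outcome has a single class; model is not identifiable")
  f <- stats::as.formula(paste("progression ~",
                               paste(spec$predictors, collapse = " + "),
                               "+ (1 | patient_id)"))
  m <- suppressMessages(
    lme4::glmer(f, data = d, family = stats::binomial()))
  sm <- summary(m)$coefficients
  conv <- length(m@optinfo$conv$lme4$messages) == 0 &&
    m@optinfo$conv$opt == 0
  list(model = m,
       coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, "Estimate"],
                                 std_error = sm[, "Std. Error"],
                                 p_value = sm[, "Pr(>|z|)"],
                                 row.names = NULL),
       ranef_sd = sqrt(unname(unlist(lme4::VarCorr(m)))[1]),
       converged = conv,
       n_obs = nrow(d), n_patients = nlevels(d$patient_id)) |>
    structure(class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Logistic mixed-effects progression model (", x$n_obs, " follow-ups, ",
      x$n_patients, " patients)\n", sep = "")
  print(x$coefficients, digits = 4)
  cat("Random patient-intercept SD:", format(x$ranef_sd, digits = 4), "\n")
  invisible(x)
}

.assign_folds <- function(d, spec) {
  set.seed(spec$fold_seed)
  if (spec$grouping == "patient") {
    g <- levels(d$patient_id)
    if (spec$n_folds > length(g))
      stop("more folds than patients under grouped assignment")
    fg <- sample(rep_len(seq_len(spec$n_folds), length(g)))
    fg[match(d$patient_id, g)]
  } else {
    sample(rep_len(seq_len(spec$n_folds), nrow(d)))
  }
}

#' Cross-validated out-of-fold progression probabilities
#'
#' Grouped k-fold cross-validation of the mixed model: every labeled
#' follow-up receives exactly one out-of-fold predicted probability. Held
#' out patients are unseen by the training fit, so prediction uses the
#' population-level linear predictor (random effect 0). Training folds
#' where the mixed model cannot be fit (single-class outcome, convergence
#' failure) fall back to a plain logistic fit, or to the smoothed training
#' class rate if even that is degenerate; fallbacks are recorded.
#'
#' @param records labeled change records.
#' @param spec a \code{\link{model_spec}}.
#' @return data.frame: the modeled rows with \code{fold}, \code{prob}
#'   (out-of-fold probability) and \code{fallback} columns.
#' @export
crossvalidate <- function(records, spec = model_spec()) {
  d <- .model_frame(records, spec$predictors)
  d$fold <- .assign_folds(d, spec)
  f <- stats::as.formula(paste("progression ~",
                               paste(spec$predictors, collapse = " + "),
                               "+ (1 | patient_id)"))
  ff <- stats::as.formula(paste("progression ~",
                                paste(spec$predictors, collapse = " + ")))
  d$prob <- NA_real_
  d$fallback <- "none"
  for (k in seq_len(spec$n_folds)) {
    tr <- d[d$fold != k, , drop = FALSE]
    te <- d[d$fold == k, , drop = FALSE]
    if (nrow(te) == 0) next
    p <- NULL; fb <- "none"
    if (length(unique(tr$progression)) >= 2) {
      m <- tryCatch(suppressMessages(suppressWarnings(
        lme4::glmer(f, data = tr, family = stats::binomial()))),
        error = function(e) NULL)
      if (!is.null(m)) {
        p <- stats::predict(m, newdata = te, re.form = NA,
                            type = "response", allow.new.levels = TRUE)
      } else {
        g <- tryCatch(suppressWarnings(
          stats::glm(ff, data = tr, family = stats::binomial())),
          error = function(e) NULL)
        if (!is.null(g)) {
          p <- stats::predict(g, newdata = te, type = "response")
          fb <- "glm"
        }
      }
    }
    if (is.null(p)) {
      p <- rep((sum(tr$progression) + 0.5) / (nrow(tr) + 1), nrow(te))
      fb <- "class-rate"
    }
    d$prob[d$fold == k] <- as.numeric(p)
    d$fallback[d$fold == k] <- fb
  }
  d
}

#' ROC curve and area under the curve
#'
#' AUC computed as the normalized Mann-Whitney U statistic (probability
#' that a random progression outranks a random non-progression; ties count
#' one half), with the full ROC point set for plotting.
#'
#' @param labels binary outcomes (0/1).
#' @param probabilities scores, higher = more likely progression.
#' @return list: \code{auc}, \code{points} (data.frame fpr, tpr ordered
#'   along the curve), \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)), all(is.finite(probabilities)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(probabilities, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(probabilities >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(th, function(t) sum(probabilities >= t & labels == 0) / n0,
                numeric(1))
  list(auc = auc,
       points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       n_pos = n1, n_neg = n0)
}

# Placement values of DeLong's structural-component estimator:
# for each positive, the fraction of negatives it outranks (ties = 1/2),
# and vice versa.
.placements <- function(labels, scores) {
  x <- scores[labels == 1]  # positives
  y <- scores[labels == 0]  # negatives
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two models scored on the same observations. The
#' covariance of the paired AUCs is estimated from DeLong's structural
#' components (placement values); the z statistic is the AUC difference
#' over the standard error of the difference, with a two-sided normal P.
#' Identical score orderings give zero variance of the difference; this is
#' flagged and P = 1 returned.
#'
#' @param labels binary outcomes shared by both models.
#' @param probs_a,probs_b the two models' scores for the same observations.
#' @return list: \code{auc_a}, \code{auc_b}, \code{statistic} (z),
#'   \code{p_value}, \code{se_diff}, \code{degenerate} flag.
#' @export
delong_test <- function(labels, probs_a, probs_b) {
  stopifnot(length(labels) == length(probs_a),
            length(labels) == length(probs_b))
  auc_a <- roc_auc(labels, probs_a)$auc
  auc_b <- roc_auc(labels, probs_b)$auc
  pa <- .placements(labels, probs_a)
  pb <- .placements(labels, probs_b)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    return(list(auc_a = auc_a, auc_b = auc_b, statistic = 0,
                p_value = 1, se_diff = 0, degenerate = TRUE))
  }
  z <- (auc_a - auc_b) / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)), se_diff = sqrt(var_diff),
       degenerate = FALSE)
}

#' Variance of a single AUC by DeLong's estimator
#' @inheritParams delong_test
#' @param probs model scores.
#' @return variance of the AUC estimate.
#' @export
delong_auc_variance <- function(labels, probs) {
  p <- .placements(labels, probs)
  stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
}

#' Exact binomial test of classification accuracy against chance
#'
#' Upper-tail exact binomial probability P(X >= correct | total, nir):
#' the chance of classifying at least this many follow-ups correctly if the
#' classifier only knew the no-information rate (the marginal progression
#' rate, i.e. the accuracy of always predicting the majority class).
#'
#' @param correct number of correctly classified follow-ups.
#' @param total number of classified follow-ups.
#' @param nir no-information rate in (0, 1).
#' @return one-sided P-value.
#' @export
binomial_accuracy_test <- function(correct, total, nir) {
  stopifnot(correct >= 0, correct <= total, nir > 0, nir < 1)
  stats::pbinom(correct - 1, total, nir, lower.tail = FALSE)
}

#' Fit, cross-validate and compare the two competing models
#'
#' The head-to-head analysis: a delta-volume model (dCV + dFV) versus a
#' regional-subtraction model (sCV + sFV), each fit as a logistic mixed
#' model and evaluated by grouped k-fold cross-validation; their
#' out-of-fold ROC curves are compared with DeLong's test, and each model's
#' cross-validated accuracy (0.5 probability threshold) is tested against
#' the no-information rate with the exact binomial test. Both AUC
#' conventions are reported: pooled over all out-of-fold predictions and
#' the mean of per-fold AUCs.
#'
#' @param records labeled change records.
#' @param n_folds,fold_seed,grouping see \code{\link{model_spec}}.
#' @return list of class \code{model_comparison}: per-model results
#'   (\code{delta}, \code{subtraction}: fit, cv predictions, pooled and
#'   per-fold-mean AUC, accuracy, binomial P), \code{delong}, \code{nir},
#'   and the full four-predictor fit (\code{joint}).
#' @export
compare_models <- function(records, n_folds = 5L, fold_seed = 1L,
                           grouping = "patient") {
  spec_d <- model_spec(c("dcv", "dfv"), n_folds, fold_seed, grouping)
  spec_s <- model_spec(c("scv", "sfv"), n_folds, fold_seed, grouping)
  spec_j <- model_spec(c("dcv", "dfv", "scv", "sfv"), n_folds, fold_seed,
                       grouping)
  joint <- fit_glmm(records, spec_j)
  eval_one <- function(spec) {
    fit <- fit_glmm(records, spec)
    cv <- crossvalidate(records, spec)
    roc <- roc_auc(cv$progression, cv$prob)
    fold_aucs <- vapply(split(cv, cv$fold), function(f) {
      if (length(unique(f$progression)) < 2) return(NA_real_)
      roc_auc(f$progression, f$prob)$auc
    }, numeric(1))
    correct <- sum((cv$prob >= 0.5) == (cv$progression == 1))
    list(fit = fit, cv = cv, auc = roc$auc, roc = roc,
         auc_fold_mean = mean(fold_aucs, na.rm = TRUE),
         accuracy = correct / nrow(cv), correct = correct, n = nrow(cv))
  }
  delta <- eval_one(spec_d)
  subtraction <- eval_one(spec_s)
  stopifnot(identical(delta$cv$progression, subtraction$cv$progression))
  labels <- delta$cv$progression
  nir <- max(mean(labels), 1 - mean(labels))
  delta$binomial_p <- binomial_accuracy_test(delta$correct, delta$n, nir)
  subtraction$binomial_p <-
    binomial_accuracy_test(subtraction$correct, subtraction$n, nir)
  dl <- delong_test(labels, delta$cv$prob, subtraction$cv$prob)
  structure(list(joint = joint, delta = delta, subtraction = subtraction,
                 delong = dl, nir = nir),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Progression model comparison (", x$delta$n, " follow-ups, NIR = ",
      format(x$nir, digits = 3), ")\n", sep = "")
  cat(sprintf("  delta model (dCV+dFV):        AUC %.3f, accuracy %.3f, binomial P %.4f\n",
              x$delta$auc, x$delta$accuracy, x$delta$binomial_p))
  cat(sprintf("  subtraction model (sCV+sFV):  AUC %.3f, accuracy %.3f, binomial P %.4f\n",
              x$subtraction$auc, x$subtraction$accuracy,
              x$subtraction$binomial_p))
  cat(sprintf("  DeLong z = %.3f, P = %.4f\n", x$delong$statistic,
              x$delong$p_value))
  cat("Joint four-predictor model:\n")
  print(x$joint$coefficients, digits = 4)
  invisible(x)
}
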