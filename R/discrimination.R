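# Finger motor impairment score: forward stepwise logistic regression
# (likelihood-ratio entry, age forced), ROC with DeLong confidence interval,
# and leave-one-out cross-validation of the final model.

DEFAULT_CANDIDATES <- c("rate_sv", "rate_mv", "td_hz2", "iti_hz2", "log_ihi")

.logit_response <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("HC", "MS"))) {
      stop("character labels must be HC/MS")
    }
    return(as.integer(labels == "MS"))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1 or HC/MS)")
  y
}

.fit_logistic <- function(x, y) {
  # x: model matrix including intercept column
  fit <- suppressWarnings(
    glm.fit(x, y, family = binomial(), control = list(maxit = 100))
  )
  fit
}

.separated <- function(fit) {
  eps <- 1e-8
  mu <- fit$fitted.values
  all(mu[fit$y == 1] > 1 - 1e-4) && all(mu[fit$y == 0] < 1e-4) ||
    any(abs(coef(fit)) > 15) && all(mu > 1 - eps | mu < eps)
}

.ridge_logistic <- function(x, y, lambda = 1e-2) {
  nll <- function(beta) {
    eta <- drop(x %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda / 2 * sum(beta[-1L]^2)
  }
  gr <- function(beta) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, mu - y))
    g[-1L] <- g[-1L] + lambda * beta[-1L]
    g
  }
  opt <- optim(rep(0, ncol(x)), nll, gr, method = "BFGS",
               control = list(maxit = 500))
  opt$par
}

#' Forward stepwise logistic regression for the impairment score
#'
#' Builds `group ~ age + selected motor features` by forward selection with a
#' likelihood-ratio entry test at `alpha_enter`; the forced covariates (age)
#' are always in the model and never tested for removal. The inter-hand
#' interval must enter as its natural log (`log_ihi`), reflecting its skewed
#' distribution.
#'
#' @param features data.frame holding the candidate columns and forced
#'   covariates; no missing values in candidates.
#' @param labels group labels (`"HC"`/`"MS"`, factor, or 0/1 with 1 = MS).
#' @param candidates candidate feature columns (default the five motor
#'   parameters with IHI log-transformed).
#' @param forced always-included covariates (default `"age"`; may be empty).
#' @param alpha_enter likelihood-ratio entry threshold (default 0.05).
#' @return A `fmi_model`: selected features, coefficients with standard
#'   errors, odds ratios with 95% CIs, intercept, forced covariates, and a
#'   `separation` flag (penalized-ridge fallback coefficients when the MLE
#'   diverges).
#' @export
stepwise_logistic <- function(features, labels,
                              candidates = DEFAULT_CANDIDATES,
                              forced = "age", alpha_enter = 0.05) {
  y <- .logit_response(labels)
  features <- as.data.frame(features)
  missing_cols <- setdiff(c(candidates, forced), names(features))
  if (length(missing_cols)) {
    stop("features is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!complete.cases(features[c(candidates, forced)]))) {
    stop("candidate/forced columns must not contain missing values")
  }
  n <- length(y)
  base_cols <- forced
  selected <- character()
  mk <- function(cols) {
    cbind(`(Intercept)` = rep(1, n),
          as.matrix(features[, cols, drop = FALSE]))
  }
  current <- .fit_logistic(mk(base_cols), y)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    devs <- vapply(remaining, function(f) {
      fit <- .fit_logistic(mk(c(base_cols, selected, f)), y)
      fit$deviance
    }, numeric(1))
    lr <- current$deviance - devs
    pvals <- pchisq(pmax(lr, 0), df = 1, lower.tail = FALSE)
    best <- which.min(pvals)
    if (pvals[best] < alpha_enter) {
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
      current <- .fit_logistic(mk(c(base_cols, selected)), y)
    } else break
  }
  x <- mk(c(base_cols, selected))
  fit <- .fit_logistic(x, y)
  separation <- .separated(fit)
  if (!fit$converged && !separation) {
    stop("logistic fit failed to converge (deviance ",
         format(fit$deviance), ")")
  }
  if (separation) {
    warning("complete or quasi-complete separation detected; ",
            "coefficients from penalized (ridge) fallback")
    beta <- .ridge_logistic(x, y)
    names(beta) <- colnames(x)
    se <- rep(NA_real_, length(beta))
  } else {
    beta <- coef(fit)
    # dispersion-free binomial covariance from the final IRLS weights
    w <- fit$weights
    xtwx <- crossprod(x * sqrt(w))
    se <- sqrt(diag(solve(xtwx)))
  }
  names(se) <- names(beta)
  motor <- selected
  or <- exp(beta[motor])
  ci <- cbind(lower = exp(beta[motor] - 1.96 * se[motor]),
              upper = exp(beta[motor] + 1.96 * se[motor]))
  structure(
    list(features = motor, forced = forced,
         coefficients = beta, se = se,
         odds_ratio = or, or_ci = ci,
         intercept = unname(beta["(Intercept)"]),
         transforms = c(ihi = "log"),
         alpha_enter = alpha_enter, n = n,
         separation = separation, deviance = fit$deviance),
    class = "fmi_model"
  )
}

#' @export
print.fmi_model <- function(x, ...) {
  cat("<fmi_model> finger motor impairment score\n")
  cat("  selected:", if (length(x$features)) paste(x$features, collapse = ", ")
      else "(none beyond forced covariates)", "\n")
  cat("  forced  :", paste(x$forced, collapse = ", "), "\n")
  for (f in x$features) {
    cat(sprintf("  %-8s OR = %.3f (95%% CI %.3f-%.3f)\n", f,
                x$odds_ratio[[f]], x$or_ci[f, "lower"], x$or_ci[f, "upper"]))
  }
  if (x$separation) cat("  [separation: penalized fallback coefficients]\n")
  invisible(x)
}

#' Finger motor impairment score
#'
#' Linear predictor of the fitted logistic model over the selected motor
#' features only (transformations applied; the age adjustment covariate is
#' excluded so that the score reflects motor impairment, not age). Higher
#' scores are more MS-like (more impaired).
#'
#' @param model a `fmi_model` from [stepwise_logistic()].
#' @param features data.frame with the selected feature columns.
#' @return Numeric score per row of `features`.
#' @export
fmi_score <- function(model, features) {
  stopifnot(inherits(model, "fmi_model"))
  features <- as.data.frame(features)
  missing_cols <- setdiff(model$features, names(features))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  score <- rep(model$intercept, nrow(features))
  for (f in model$features) {
    if (any(is.na(features[[f]]))) {
      stop("missing values in feature ", f)
    }
    score <- score + model$coefficients[[f]] * features[[f]]
  }
  score
}

.delong_components <- function(pos, neg) {
  # mid-rank structural components: V10_i = mean_j psi(x_i, y_j)
  n1 <- length(pos); n0 <- length(neg)
  all <- c(pos, neg)
  r_all <- rank(all)
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01)
}

#' Empirical ROC curve and AUC with DeLong inference
#'
#' AUC is computed through the rank (Mann-Whitney) identity with midpoint tie
#' handling (trapezoidal ROC). The confidence interval and the p value
#' against AUC = 0.5 use the DeLong variance.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels binary labels (`"HC"`/`"MS"` or 0/1; MS/1 is the positive
#'   class).
#' @param conf confidence level (default 0.95).
#' @return A `roc_result`: `auc`, `ci`, `p`, `se`, `curve` (FPR/TPR points
#'   from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  y <- .logit_response(labels)
  if (!any(y == 1) || !any(y == 0)) {
    stop("both classes must be present to compute a ROC curve")
  }
  keep <- !is.na(scores)
  scores <- scores[keep]; y <- y[keep]
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  dc <- .delong_components(pos, neg)
  v <- var(dc$v10) / n1 + var(dc$v01) / n0
  se <- sqrt(max(v, 0))
  zq <- qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * pnorm(-abs(auc - 0.5) / se)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- unique(curve[order(curve$fpr, curve$tpr), , drop = FALSE])
  rownames(curve) <- NULL
  structure(list(auc = auc, se = se, ci = ci, p = p, conf = conf,
                 curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%.0f%% CI %.3f-%.3f, p = %.3g); %d pos / %d neg\n",
              x$auc, 100 * x$conf, x$ci[1], x$ci[2], x$p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Leave-one-out cross-validated discrimination
#'
#' For each subject, refits the logistic model on the remaining `n - 1`
#' subjects and scores the held-out subject with the full linear predictor
#' (forced covariates included); the ROC is computed over the out-of-fold
#' scores. By default the final feature set is held fixed across folds (the
#' final model is being evaluated); `reselect = TRUE` re-runs stepwise
#' selection inside each fold instead.
#'
#' @param features data.frame of candidate/forced columns.
#' @param labels binary labels.
#' @param selected feature set of the final model (required unless
#'   `reselect = TRUE`).
#' @param forced forced covariates (default `"age"`).
#' @param reselect re-run forward selection within each fold.
#' @param candidates candidate set used when `reselect = TRUE`.
#' @param alpha_enter entry threshold when `reselect = TRUE`.
#' @return A `roc_result` over out-of-fold scores, with `oof_scores` and
#'   `failed_folds` attached.
#' @export
loo_cv_auc <- function(features, labels, selected, forced = "age",
                       reselect = FALSE, candidates = DEFAULT_CANDIDATES,
                       alpha_enter = 0.05) {
  y <- .logit_response(labels)
  features <- as.data.frame(features)
  n <- length(y)
  if (n < 10L) stop("leave-one-out evaluation requires n >= 10")
  oof <- rep(NA_real_, n)
  failed <- integer()
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    cols <- if (reselect) {
      m <- tryCatch(
        stepwise_logistic(features[tr, , drop = FALSE], y[tr],
                          candidates = candidates, forced = forced,
                          alpha_enter = alpha_enter),
        error = function(e) NULL)
      if (is.null(m)) { failed <- c(failed, i); next }
      c(forced, m$features)
    } else {
      c(forced, selected)
    }
    x_tr <- cbind(1, as.matrix(features[tr, cols, drop = FALSE]))
    fit <- tryCatch(.fit_logistic(x_tr, y[tr]), error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, i); next }
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    x_i <- c(1, as.numeric(features[i, cols]))
    oof[i] <- sum(x_i * beta)
  }
  if (length(failed)) {
    warning(length(failed), " fold(s) failed to refit and were dropped: ",
            paste(head(failed, 5), collapse = ", "))
  }
  ok <- !is.na(oof)
  res <- roc_auc(oof[ok], y[ok])
  res$oof_scores <- oof
  res$failed_folds <- failed
  res
}
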