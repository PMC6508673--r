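#' Pearson product-moment correlation
#'
#' Thin wrapper around the product-moment correlation with the input checks
#' the stepwise selection procedure relies on (the correlation gate between
#' candidate and already-selected metrics is |r| < 0.5).
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("degenerate input: zero variance.")
  }
  stats::cor(x, y, method = "pearson")
}

## ridge-penalised Newton fit, used when the ML fit separates perfectly
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 200L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- inv_logit(eta)
    w <- p * (1 - p)
    grad <- drop(crossprod(X, y - p)) - lambda * beta
    hess <- crossprod(X * w, X) + diag(lambda, ncol(X))
    step <- solve(hess, grad)
    beta_new <- beta + step
    if (max(abs(step)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Fit a logistic regression for ghost-forest classification
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary response on a set of metric
#' columns, reporting coefficients, log-likelihood and AIC = 2k - 2 logLik.
#' If the fit separates perfectly (fitted probabilities numerically 0 or 1),
#' a warning is issued and a tiny ridge penalty (1e-6) keeps the
#' coefficients finite.
#'
#' @param data Data frame containing the response and metric columns.
#' @param response Name of the binary (0/1 or logical) response column.
#' @param terms Character vector of predictor column names (may be empty for
#'   an intercept-only model).
#' @return A `logistic_fit` list: `coefficients` (named, intercept first),
#'   `log_lik`, `aic`, `terms`, `separation` flag.
#' @export
fit_logistic <- function(data, response = "ghost", terms = character()) {
  y <- as.numeric(data[[response]])
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("response must be binary with no missing values.")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, terms, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("rank-deficient design matrix.")

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- fit$coefficients
  if (separated) {
    warn("possible perfect separation; using a ridge-stabilised fit.")
    beta <- ridge_logistic(X, y)
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  k <- length(beta)
  structure(
    list(
      coefficients = setNames(as.numeric(beta), colnames(X)),
      log_lik = ll,
      aic = 2 * k - 2 * ll,
      terms = terms,
      response = response,
      separation = separated
    ),
    class = "logistic_fit"
  )
}

#' Predicted ghost-forest probabilities
#'
#' @param object A `logistic_fit`.
#' @param newdata Data frame containing the fit's metric columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$terms, drop = FALSE]))
  inv_logit(drop(X %*% object$coefficients))
}

#' Correlation-constrained stepwise AIC selection of vegetation metrics
#'
#' Selects the vegetation metrics that best predict ghost forest.  Step 1
#' fits a single-metric logistic model for every metric and keeps the one
#' with the lowest AIC.  Each later step considers only the remaining metrics
#' whose Pearson correlation with *every* already-selected metric is below
#' `corr_threshold` in absolute value, fits each candidate added to the
#' current model, and accepts the best candidate only if it strictly lowers
#' AIC; otherwise the more parsimonious model is retained and selection
#' stops.  Selection also stops when no correlation-eligible candidate
#' remains.
#'
#' @param data Data frame of metric columns plus the binary response.
#' @param response Name of the binary response column.
#' @param metrics Character vector of candidate metric columns (default: all
#'   columns except the response).
#' @param corr_threshold Absolute-correlation gate between a candidate and
#'   every selected metric (default 0.5).
#' @return A `stepwise_result` list: `selected` (ordered metric names),
#'   `steps` (tibble of every candidate model: step, candidate, model terms,
#'   log-likelihood, AIC, delta-AIC within step, accepted flag), and `fit`
#'   (the final `logistic_fit`).
#' @export
stepwise_select <- function(data, response = "ghost",
                            metrics = setdiff(names(data), response),
                            corr_threshold = 0.5) {
  if (length(metrics) < 2L) abort("need at least 2 candidate metrics.")
  y <- as.numeric(data[[response]])
  if (length(unique(y)) < 2L) {
    abort("response must contain both classes.")
  }

  selected <- character()
  current_aic <- Inf
  rows <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(metrics, selected)
    eligible <- remaining[vapply(remaining, function(m) {
      all(vapply(selected, function(s) {
        abs(pearson_correlation(data[[m]], data[[s]])) < corr_threshold
      }, logical(1)))
    }, logical(1))]
    if (!length(eligible)) break

    fits <- lapply(eligible, function(m) {
      fit_logistic(data, response, c(selected, m))
    })
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    accepted <- aics[best] < current_aic
    rows[[step]] <- tibble::tibble(
      step = step,
      candidate = eligible,
      model = vapply(eligible, function(m) {
        paste(c(selected, m), collapse = " + ")
      }, character(1)),
      log_lik = vapply(fits, `[[`, numeric(1), "log_lik"),
      aic = aics,
      delta_aic = aics - min(aics),
      accepted = accepted & seq_along(eligible) == best
    )
    if (!accepted) break
    selected <- c(selected, eligible[best])
    current_aic <- aics[best]
  }

  if (!length(selected)) abort("no metric improved on the null model.")
  structure(
    list(
      selected = selected,
      steps = dplyr::bind_rows(rows),
      fit = fit_logistic(data, response, selected),
      corr_threshold = corr_threshold
    ),
    class = "stepwise_result"
  )
}

#' Exhaustive search over correlation-feasible metric subsets
#'
#' Reference procedure used to validate the stepwise selection: enumerates
#' every non-empty subset of the metrics whose pairwise absolute correlations
#' are all below the threshold, fits each by ordinary [stats::glm()]
#' logistic regression, and returns the subset with the lowest AIC.
#'
#' @inheritParams stepwise_select
#' @return A list: `selected` (metric names, unordered) and `aic`.
#' @export
exhaustive_select <- function(data, response = "ghost",
                              metrics = setdiff(names(data), response),
                              corr_threshold = 0.5) {
  y <- as.numeric(data[[response]])
  cors <- abs(stats::cor(as.matrix(data[, metrics, drop = FALSE])))
  best <- NULL
  best_aic <- Inf
  n_m <- length(metrics)
  for (code in seq_len(2^n_m - 1L)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n_m) - 1L)) > 0)
    sub <- metrics[idx]
    if (length(sub) > 1L && any(cors[sub, sub][upper.tri(cors[sub, sub])] >=
                                corr_threshold)) next
    df <- data.frame(y = y, data[, sub, drop = FALSE])
    a <- suppressWarnings(
      stats::AIC(stats::glm(y ~ ., data = df, family = binomial()))
    )
    if (a < best_aic) {
      best_aic <- a
      best <- sub
    }
  }
  list(selected = best, aic = best_aic)
}

#' Class-stratified train/validation split
#'
#' Splits row indices into a training and a validation set (default 60/40),
#' stratified by the binary response so both sets keep the overall class
#' proportions.
#'
#' @param labels Binary (0/1 or logical) class labels.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `validation`;
#'   disjoint and exhaustive.
#' @export
split_train_validation <- function(labels, train_fraction = 0.6, seed = 1) {
  check_fraction(train_fraction, "train_fraction")
  check_seed(seed)
  labels <- as.numeric(labels)
  if (any(table(labels) < 2L) || length(unique(labels)) < 2L) {
    abort("each class needs at least 2 members for a stratified split.")
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Holdout sensitivity and specificity of a ghost-forest classifier
#'
#' Classifies validation points as ghost where the predicted probability is
#' at least `prob_threshold`, and reports sensitivity = TP / (TP + FN) on the
#' ghost class and specificity = TN / (TN + FP) on the unaffected class.  A
#' metric whose class is absent from the validation set is reported as `NA`.
#'
#' @param fit A `logistic_fit`.
#' @param validation Data frame of validation rows (metrics + response).
#' @param prob_threshold Classification threshold on the predicted
#'   probability.
#' @return A tibble with columns `sensitivity` and `specificity`.
#' @export
evaluate_sensitivity_specificity <- function(fit, validation,
                                             prob_threshold = 0.5) {
  stopifnot(inherits(fit, "logistic_fit"))
  y <- as.numeric(validation[[fit$response]])
  pred <- as.numeric(predict(fit, validation) >= prob_threshold)
  sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
  spec <- if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec)
}
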