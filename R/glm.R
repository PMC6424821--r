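#' Spike counts per theta cycle
#'
#' Counts each neuron's spikes within every retained (valid) theta cycle,
#' half-open `[start, next start)`. Theta cycles provide the natural time
#' windows for hippocampal ensemble expression, so they serve as the
#' observation bins for ensemble-to-ensemble prediction.
#'
#' @param spikes spike trains.
#' @param cycles a [theta_cycles] object.
#' @return object of class `cycle_counts`: `counts` (cycles x neurons integer
#'   matrix), `starts`, `ends` (retained cycle boundaries).
#' @export
bin_by_cycles <- function(spikes, cycles) {
  trains <- as_spike_trains(spikes)
  keep <- which(cycles$valid)
  starts <- cycles$boundaries[keep]
  ends <- cycles$boundaries[keep + 1]
  counts <- vapply(trains, function(ts) {
    idx <- findInterval(ts, cycles$boundaries)
    idx <- idx[idx >= 1 & idx <= length(cycles$lengths)]
    tabulate(match(idx, keep), nbins = length(keep))
  }, integer(length(keep)))
  counts <- matrix(counts, nrow = length(keep),
                   dimnames = list(NULL, names(trains)))
  structure(list(counts = counts, starts = starts, ends = ends),
            class = "cycle_counts")
}

#' Fit an ensemble spike-count prediction model
#'
#' Predicts a target neuron's per-cycle spike count from the simultaneously
#' recorded predictor population: `target(theta) = b0 + sum_i b_i x_i(theta)
#' + error`. The default family is Gaussian with identity link (ordinary
#' least squares, matching the linear form of the written model); a
#' log-link Poisson family is available. Predictors are raw per-neuron cycle
#' counts by default; optionally they are first compressed onto their top
#' principal components.
#'
#' @param target integer vector of per-cycle target counts.
#' @param predictors cycles x neurons matrix of predictor counts.
#' @param family `"gaussian"` (identity link, default) or `"poisson"`
#'   (log link).
#' @param pca if `TRUE`, regress on the top `n_pc` principal components of
#'   the predictors instead of raw counts.
#' @param n_pc number of components when `pca = TRUE`.
#' @param training_id optional label of the training session.
#' @return object of class `ensemble_model`: `intercept`, `coef` (one per
#'   predictor column), `family`, `pca` (rotation or `NULL`),
#'   `training_id`, `r2_train`.
#' @export
fit_ensemble_model <- function(target, predictors,
                               family = c("gaussian", "poisson"),
                               pca = FALSE, n_pc = NULL, training_id = NULL) {
  family <- match.arg(family)
  X <- as.matrix(predictors)
  y <- as.numeric(target)
  stopifnot(length(y) == nrow(X))
  if (nrow(X) <= ncol(X) + 1)
    stop("need more cycles than predictors + 1")
  pca_spec <- NULL
  if (pca) {
    if (is.null(n_pc)) n_pc <- min(10L, ncol(X))
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    pca_spec <- list(center = pc$center,
                     rotation = pc$rotation[, seq_len(n_pc), drop = FALSE])
    X <- pc$x[, seq_len(n_pc), drop = FALSE]
  }
  Xd <- cbind(`(Intercept)` = 1, X)

  if (family == "gaussian") {
    fit <- lm.fit(Xd, y)
    beta <- fit$coefficients
    if (anyNA(beta)) {
      message("rank-deficient predictors; falling back to ridge (penalty 1e-6)")
      lambda <- 1e-6 * mean(diag(crossprod(Xd)))
      beta <- solve(crossprod(Xd) + lambda * diag(ncol(Xd)), crossprod(Xd, y))
      beta <- drop(beta)
    }
    pred <- drop(Xd %*% beta)
  } else {
    fit <- suppressWarnings(glm.fit(Xd, y, family = poisson()))
    beta <- fit$coefficients
    if (anyNA(beta)) {
      message("rank-deficient predictors; dropping aliased columns")
      beta[is.na(beta)] <- 0
    }
    pred <- exp(drop(Xd %*% beta))
  }
  r2 <- if (stats::var(y) > 0) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
        else NA_real_
  structure(list(intercept = unname(beta[1]), coef = beta[-1],
                 family = family, pca = pca_spec,
                 training_id = training_id, r2_train = r2),
            class = "ensemble_model")
}

#' Predict per-cycle counts and score accuracy
#'
#' Applies an [fit_ensemble_model] fit to a (possibly different) session's
#' predictor matrix and quantifies accuracy as the Pearson correlation
#' between the observed target counts and the model predictions across
#' cycles.
#'
#' @param model an `ensemble_model`.
#' @param predictors cycles x neurons matrix matching the model's predictor
#'   ids.
#' @param observed observed per-cycle target counts.
#' @return list `accuracy` (correlation; `NA` with a message when observed or
#'   predicted counts have zero variance) and `predicted`.
#' @export
predict_and_score <- function(model, predictors, observed) {
  X <- as.matrix(predictors)
  if (!is.null(model$pca)) {
    X <- sweep(X, 2, model$pca$center) %*% model$pca$rotation
  } else if (!is.null(names(model$coef)) && !is.null(colnames(X))) {
    if (!all(names(model$coef) %in% colnames(X)))
      stop("predictor ids do not match the model's")
    X <- X[, names(model$coef), drop = FALSE]
  }
  eta <- model$intercept + drop(X %*% model$coef)
  pred <- if (model$family == "poisson") exp(eta) else eta
  obs <- as.numeric(observed)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    message("zero-variance observed or predicted counts; accuracy undefined")
    return(list(accuracy = NA_real_, predicted = pred))
  }
  list(accuracy = cor(obs, pred), predicted = pred)
}
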