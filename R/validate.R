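# Site-grouped k-fold cross-validation and temporal external validation.
#
# Fold unit is the monitoring site, not the row: all periods of a site are
# held out together, so every site serves as a validation benchmark exactly
# once over the k folds.

#' Assign stations to cross-validation folds
#'
#' Uniform random partition of stations into `k` folds whose sizes differ by
#' at most one, reproducible from `seed`.
#'
#' @param station_ids character vector of unique station ids (a station data
#'   frame is also accepted).
#' @param k number of folds, at least 2 and at most the number of stations.
#' @param seed integer RNG seed.
#' @return object of class `fold_assignment`: named integer vector mapping
#'   station id to fold in 1..k, with attributes `k` and `seed`.
#' @export
make_site_folds <- function(station_ids, k, seed) {
  if (is.data.frame(station_ids)) station_ids <- station_ids$station_id
  station_ids <- as.character(station_ids)
  if (anyDuplicated(station_ids)) stopf("station ids must be unique")
  ns <- length(station_ids)
  if (k < 2) stopf("k must be at least 2")
  if (k > ns) stopf("k (%d) exceeds the number of stations (%d)", k, ns)
  folds <- with_seed(seed, {
    sizes <- rep(ns %/% k, k) + c(rep(1, ns %% k), rep(0, k - ns %% k))
    sample(rep(seq_len(k), times = sizes))
  })
  structure(stats::setNames(as.integer(folds), station_ids),
            k = as.integer(k), seed = as.integer(seed),
            class = "fold_assignment")
}

# squared Pearson correlation, with the degenerate-prediction convention:
# zero-variance predictions (e.g. every fold returned an intercept-only
# model) carry no information and score 0.
r2_pearson <- function(obs, pred) {
  if (length(obs) < 2 || sd(pred) == 0 || sd(obs) == 0) return(0)
  cor(obs, pred)^2
}

r2_sse <- function(obs, pred) {
  tss <- sum((obs - mean(obs))^2)
  if (tss <= 0) return(0)
  1 - sum((obs - pred)^2) / tss
}

#' Site-grouped cross-validation of the LUR pipeline
#'
#' For each fold, the model is developed on the training ~90% and used to
#' predict the held-out sites' rows. By default the full forward selection is
#' re-run inside every fold (`mode = "reselect"`), so the variable-selection
#' uncertainty is included in the validation; `mode = "refit"` instead keeps
#' the term set of `model` fixed and only re-estimates its coefficients per
#' fold.
#'
#' Pooled statistics are computed from out-of-fold predictions only. Two R2
#' conventions are reported: `cv_r2`, the squared Pearson correlation between
#' pooled out-of-fold predictions and observations, and `cv_r2_sse`,
#' `1 - SSE/SST` on the same pooled pairs.
#'
#' @param design a `predictor_table` (must contain `station_id`).
#' @param response numeric response vector, same row order as `design`.
#' @param folds a `fold_assignment` covering every station in `design`.
#' @param config a [selection_config()].
#' @param mode `"reselect"` (default) or `"refit"`.
#' @param model fitted `lur_model`; required for `mode = "refit"`.
#' @param priors optional sign priors (defaults to the design metadata).
#' @return object of class `lur_cv`: `per_fold` data frame (fold, n, r2,
#'   rmse, n_terms, failed), `cv_r2`, `cv_r2_sse`, `cv_rmse`, the pooled
#'   `predictions` data frame, `mode` and the R2 `definitions` tag.
#' @export
cross_validate <- function(design, response, folds,
                           config = selection_config(),
                           mode = c("reselect", "refit"), model = NULL,
                           priors = NULL) {
  mode <- match.arg(mode)
  if (!inherits(folds, "fold_assignment")) stopf("folds must come from make_site_folds()")
  if (mode == "refit" && !inherits(model, "lur_model")) {
    stopf("mode = 'refit' requires a fitted model")
  }
  sid <- design$station_id
  if (is.null(sid)) stopf("design must contain station_id")
  uncovered <- setdiff(unique(sid), names(folds))
  if (length(uncovered) > 0) {
    stopf("station(s) not covered by fold assignment: %s",
          paste(uncovered, collapse = ", "))
  }
  y <- as.numeric(response)
  k <- attr(folds, "k")
  fold_of_row <- unname(folds[sid])

  pred <- rep(NA_real_, length(y))
  per_fold <- data.frame(fold = seq_len(k), n = 0L, r2 = NA_real_,
                         rmse = NA_real_, n_terms = NA_integer_,
                         failed = FALSE)
  for (f in seq_len(k)) {
    test <- which(fold_of_row == f)
    train <- which(fold_of_row != f)
    per_fold$n[f] <- length(test)
    if (length(test) == 0) next
    fold_fit <- tryCatch({
      if (mode == "reselect") {
        m <- forward_select(subset_design(design, train), y[train], config,
                            priors = priors)
      } else {
        m <- refit_terms(design, y, train, model, config)
      }
      m
    }, error = function(e) e)
    if (inherits(fold_fit, "error")) {
      per_fold$failed[f] <- TRUE
      next
    }
    ptest <- predict_at_points(fold_fit, design[test, , drop = FALSE])
    pred[test] <- ptest
    per_fold$r2[f] <- r2_pearson(y[test], ptest)
    per_fold$rmse[f] <- sqrt(mean((y[test] - ptest)^2))
    per_fold$n_terms[f] <- nrow(fold_fit$terms)
  }
  ok <- !is.na(pred)
  out <- list(
    per_fold = per_fold,
    cv_r2 = r2_pearson(y[ok], pred[ok]),
    cv_r2_sse = r2_sse(y[ok], pred[ok]),
    cv_rmse = sqrt(mean((y[ok] - pred[ok])^2)),
    predictions = data.frame(station_id = sid, fold = fold_of_row,
                             observed = y, predicted = pred,
                             stringsAsFactors = FALSE),
    mode = mode, k = k, seed = attr(folds, "seed"),
    definitions = "cv_r2: squared Pearson correlation of pooled out-of-fold predictions vs observations; cv_r2_sse: 1 - SSE/SST on the same pairs"
  )
  class(out) <- "lur_cv"
  out
}

subset_design <- function(design, rows) {
  out <- as.data.frame(design)[rows, , drop = FALSE]
  attr(out, "column_info") <- attr(design, "column_info")
  class(out) <- class(design)
  out
}

# refit a fixed term set on a training subset (no re-selection)
refit_terms <- function(design, y, train, model, config) {
  cols <- model$terms$column
  X <- as.matrix(as.data.frame(design)[train, cols, drop = FALSE])
  yt <- y[train]
  if (config$response_transform == "log10") yt <- log10(yt)
  fit <- fit_ols(X, yt)
  out <- model
  out$intercept <- fit$intercept
  out$terms$coefficient <- unname(fit$coefficients[cols])
  out$terms$p_value <- unname(fit$p_values[cols])
  out$r2 <- fit$r2
  out$adjusted_r2 <- fit$adjusted_r2
  out$rmse <- fit$rmse
  out$n_obs <- fit$n_obs
  out
}

#' @export
print.lur_cv <- function(x, ...) {
  cat(sprintf("<lur_cv> %d-fold site-grouped CV (%s): cv_r2 = %.4f, cv_r2_sse = %.4f, cv_rmse = %.4g\n",
              x$k, x$mode, x$cv_r2, x$cv_r2_sse, x$cv_rmse))
  invisible(x)
}

#' Temporal external validation
#'
#' Develops the model on all periods before `holdout_year` and evaluates it
#' on the held-out year only, mirroring the practice of validating an
#' exposure model against a later monitoring year it never saw.
#'
#' @inheritParams cross_validate
#' @param holdout_year integer year used only for evaluation; must be present
#'   in `design$year`, and at least one earlier period must exist.
#' @return list of class `lur_external`: the trained `model`, `external_r2`
#'   (squared Pearson, with `external_r2_sse` alongside), `external_rmse`,
#'   `n_holdout`, `holdout_year`, and the holdout `predictions`.
#' @export
external_validate <- function(design, response, holdout_year,
                              config = selection_config(),
                              mode = c("reselect", "refit"), model = NULL,
                              priors = NULL) {
  mode <- match.arg(mode)
  if (mode == "refit" && !inherits(model, "lur_model")) {
    stopf("mode = 'refit' requires a fitted model")
  }
  yr <- design$year
  if (is.null(yr)) stopf("design must contain a year column")
  holdout <- which(yr == holdout_year)
  if (length(holdout) == 0) stopf("holdout year %s absent from design", holdout_year)
  train <- which(yr < holdout_year)
  if (length(train) == 0) stopf("no training periods before %s", holdout_year)
  y <- as.numeric(response)
  model <- if (mode == "reselect") {
    forward_select(subset_design(design, train), y[train], config,
                   priors = priors)
  } else {
    refit_terms(design, y, train, model, config)
  }
  pred <- predict_at_points(model, design[holdout, , drop = FALSE])
  out <- list(
    model = model,
    external_r2 = r2_pearson(y[holdout], pred),
    external_r2_sse = r2_sse(y[holdout], pred),
    external_rmse = sqrt(mean((y[holdout] - pred)^2)),
    n_holdout = length(holdout), holdout_year = holdout_year,
    predictions = data.frame(station_id = design$station_id[holdout],
                             observed = y[holdout], predicted = pred,
                             stringsAsFactors = FALSE),
    definitions = "external_r2: squared Pearson correlation on holdout rows"
  )
  class(out) <- "lur_external"
  out
}

#' @export
print.lur_external <- function(x, ...) {
  cat(sprintf("<lur_external> holdout %s (n = %d): external_r2 = %.4f, rmse = %.4g\n",
              x$holdout_year, x$n_holdout, x$external_r2, x$external_rmse))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Deterministic JSON for `lur_cv` and `lur_external` objects.
#'
#' @param report a `lur_cv` or `lur_external` object.
#' @param include_predictions include the per-row prediction table.
#' @return a JSON string.
#' @export
report_to_json <- function(report, include_predictions = FALSE) {
  if (inherits(report, "lur_cv")) {
    obj <- list(schema = "lur_cv/1", k = report$k, mode = report$mode,
                seed = report$seed, cv_r2 = report$cv_r2,
                cv_r2_sse = report$cv_r2_sse, cv_rmse = report$cv_rmse,
                per_fold = report$per_fold, definitions = report$definitions)
    if (include_predictions) obj$predictions <- report$predictions
  } else if (inherits(report, "lur_external")) {
    obj <- list(schema = "lur_external/1",
                holdout_year = report$holdout_year,
                n_holdout = report$n_holdout,
                external_r2 = report$external_r2,
                external_r2_sse = report$external_r2_sse,
                external_rmse = report$external_rmse,
                model = jsonlite::fromJSON(model_to_json(report$model)),
                definitions = report$definitions)
    if (include_predictions) obj$predictions <- report$predictions
  } else {
    stopf("unsupported report class: %s", paste(class(report), collapse = "/"))
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows", na = "null")
}
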