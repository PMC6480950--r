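# Supervised sign-constrained forward selection with p-value and VIF gates,
# and the OLS core it is built on.

#' Selection configuration
#'
#' Tuning parameters of the supervised forward-selection procedure.
#'
#' @param p_enter maximum two-sided t-test p-value a candidate may have in the
#'   augmented model to be admissible (default 0.1).
#' @param vif_max upper bound (exclusive) on every variance inflation factor
#'   in the augmented model (default 3).
#' @param min_adj_r2_gain minimum adjusted-R-squared gain a candidate must
#'   deliver to enter. The default 0.01 follows the common supervised-LUR
#'   convention: with candidate sets of ~150 buffer variables, the smallest
#'   p-value among remaining candidates is almost always below `p_enter` by
#'   chance alone, so a pure p-gate never stops; requiring a 1% adjusted-R2
#'   gain is the standard guard. Set to 0 for a pure p/VIF-gated selection.
#' @param response_transform `"identity"` or `"log10"` (fit on log10 of the
#'   response; predictions are back-transformed).
#' @param max_terms maximum number of terms to enter (`Inf` = unlimited).
#' @param check_entered_signs re-check at each admission that no previously
#'   entered constrained coefficient flips sign (default `TRUE`).
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(p_enter = 0.1, vif_max = 3,
                             min_adj_r2_gain = 0.01,
                             response_transform = c("identity", "log10"),
                             max_terms = Inf, check_entered_signs = TRUE) {
  if (!is_scalar_number(p_enter) || p_enter <= 0 || p_enter >= 1) {
    stopf("p_enter must be in (0, 1)")
  }
  if (!is_scalar_number(vif_max) || vif_max <= 1) {
    stopf("vif_max must exceed 1")
  }
  structure(
    list(p_enter = p_enter, vif_max = vif_max,
         min_adj_r2_gain = min_adj_r2_gain,
         response_transform = match.arg(response_transform),
         max_terms = max_terms,
         check_entered_signs = isTRUE(check_entered_signs)),
    class = "selection_config"
  )
}

#' Ordinary least squares with the diagnostics the selection uses
#'
#' Fits `response ~ 1 + X` by QR least squares and returns the coefficient
#' estimates, their two-sided t-test p-values, R-squared, adjusted R-squared
#' and RMSE (`sqrt(mean(residuals^2))`).
#'
#' @param X numeric matrix or data frame of predictors (no intercept column).
#' @param response numeric vector.
#' @return list with `intercept`, `coefficients` (named), `p_values` (named,
#'   including `(Intercept)`), `r2`, `adjusted_r2`, `rmse`, `n_obs`,
#'   `residuals`, `fitted`. A constant response is fitted with the convention
#'   `r2 = 0` and zero slopes.
#' @export
fit_ols <- function(X, response) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(X) != n) stopf("X and response have different lengths")
  if (anyNA(X) || anyNA(y)) {
    stopf("missing values in the fit: apply complete-case filtering first")
  }
  p <- ncol(X)
  if (n <= p + 1) stopf("need n_obs > number of predictors + 1")
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- cn
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - p - 1
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  if (tss <= 0) {                      # constant response convention
    r2 <- 0
    beta[-1] <- 0
    pval[] <- 1
  } else {
    r2 <- 1 - rss / tss
  }
  adj <- if (tss <= 0) 0 else 1 - (1 - r2) * (n - 1) / df
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(beta[-1], cn),
       p_values = stats::setNames(pval, c("(Intercept)", cn)),
       r2 = r2, adjusted_r2 = adj, rmse = sqrt(rss / n), n_obs = n,
       residuals = res, fitted = fitted)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column j on
#' the remaining columns (with intercept). Perfect collinearity is reported
#' as `Inf`, not an error.
#'
#' @param X numeric matrix or data frame with at least two columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 2) stopf("VIF needs at least two columns")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zi <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Zi, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss <= 0) return(Inf)          # constant column: undefined, flag hard
    r2j <- 1 - rss / tss
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
  stats::setNames(out, cn)
}

# ---- Gram-matrix selection engine -----------------------------------------
# Selection evaluates hundreds of small candidate fits per round; all of them
# are solved from one precomputed Gram matrix of the standardized candidates
# (O(p^3) per candidate instead of O(n p^2)), which matches full QR fits to
# machine precision on these well-scaled standardized systems.

make_gram <- function(X, y) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  ys <- y - mean(y)
  list(G = crossprod(Xs), g = drop(crossprod(Xs, ys)), yy = sum(ys^2),
       n = n, mu = mu[keep], sdv = sdv[keep], ybar = mean(y),
       cols = colnames(X)[keep])
}

# fit of the subset S (integer indices into gram$cols); centered/standardized
gram_fit <- function(gram, S) {
  p <- length(S)
  n <- gram$n
  GS <- gram$G[S, S, drop = FALSE]
  ch <- tryCatch(chol(GS), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) *
                           sqrt(max(diag(GS))))) {
    return(NULL)                       # numerically singular subset
  }
  b <- backsolve(ch, forwardsolve(t(ch), gram$g[S]))
  rss <- max(gram$yy - sum(b * gram$g[S]), 0)
  df <- n - p - 1
  inv <- chol2inv(ch)
  sigma2 <- rss / df
  se <- sqrt(pmax(diag(inv), 0) * sigma2)
  tval <- ifelse(se > 0, b / se, 0)
  r2 <- if (gram$yy <= 0) 0 else 1 - rss / gram$yy
  list(b = b, p_values = 2 * pt(abs(tval), df = df, lower.tail = FALSE),
       r2 = r2, adj = if (gram$yy <= 0) 0 else 1 - (1 - r2) * (n - 1) / df,
       rss = rss)
}

gram_vif <- function(gram, S) {
  if (length(S) < 2) return(rep(1, length(S)))
  R <- gram$G[S, S, drop = FALSE] / (gram$n - 1)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) return(rep(Inf, length(S)))
  d <- diag(inv)
  ifelse(d < 0 | !is.finite(d), Inf, d)
}

#' Univariate screening of candidate predictors
#'
#' Ranks every candidate column by its univariate R-squared against the
#' response and flags eligibility: a candidate is eligible iff its univariate
#' slope sign matches its sign prior (unconstrained priors are always
#' eligible).
#'
#' @param design a `predictor_table` or numeric matrix/data frame of
#'   candidates.
#' @param response numeric response vector (same row order as `design`).
#' @param priors named character vector of sign priors; defaults to the
#'   design's column metadata when `design` is a `predictor_table`.
#' @return data frame (column, r2, slope_sign, eligible), ranked by r2
#'   descending (ties broken by column name).
#' @export
univariate_screen <- function(design, response, priors = NULL) {
  prep <- prepare_candidates(design, response, priors)
  gram <- make_gram(prep$X, prep$y)
  r2 <- ifelse(diag(gram$G) > 0, gram$g^2 / (diag(gram$G) * gram$yy), 0)
  if (gram$yy <= 0) r2[] <- 0
  sgn <- sign(gram$g)
  pr <- prep$priors[gram$cols]
  eligible <- pr == "unconstrained" | sgn == vapply(pr, prior_sign, numeric(1))
  out <- data.frame(column = gram$cols, r2 = as.numeric(r2),
                    slope_sign = as.numeric(sgn),
                    eligible = as.logical(eligible),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r2, out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared front end: extract candidate matrix, complete-case filter, priors
prepare_candidates <- function(design, response, priors = NULL,
                               transform = "identity") {
  if (inherits(design, "predictor_table")) {
    cols <- candidate_columns(design)
    priors <- priors %||% design_priors(design)
    X <- as.matrix(as.data.frame(design)[, cols, drop = FALSE])
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(priors)) {
      priors <- stats::setNames(rep("unconstrained", ncol(X)), colnames(X))
    }
  }
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  if (length(y) != nrow(X)) stopf("design and response have different lengths")
  if (transform == "log10") {
    if (any(y[!is.na(y)] <= 0)) stopf("log10 transform needs a positive response")
    y <- log10(y)
  }
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  miss <- setdiff(colnames(X), names(priors))
  if (length(miss) > 0) {
    stopf("no sign prior supplied for column(s): %s",
          paste(miss, collapse = ", "))
  }
  list(X = X, y = y, priors = priors, rows = which(cc))
}

#' Supervised sign-constrained forward selection
#'
#' Builds a land-use-regression model by the supervised stepwise procedure:
#' the model is seeded with the candidate of highest univariate R-squared
#' whose slope has the a-priori expected direction; each subsequent round,
#' every remaining candidate is added alone to the current model and is
#' admissible iff (i) its own p-value is below `p_enter`, (ii) its own
#' coefficient sign matches its prior, (iii) no previously entered
#' constrained coefficient flips sign, and (iv) all VIFs of the augmented
#' model are below `vif_max`. Among admissible candidates the one with the
#' largest adjusted-R-squared gain (required to exceed `min_adj_r2_gain`)
#' enters; ties break by smaller candidate p-value, then lexicographic column
#' name. Entered terms are never removed, even if their p-value later rises
#' above `p_enter`. Selection stops when no candidate is admissible or
#' `max_terms` is reached.
#'
#' @inheritParams univariate_screen
#' @param config a [selection_config()].
#' @return an object of class `lur_model`: intercept, ordered `terms` data
#'   frame (column, coefficient, p_value at the final fit, incremental_r2 at
#'   entry, sign_prior), `r2`, `adjusted_r2`, `rmse`, `n_obs`,
#'   `response_transform` and the config used. An intercept-only model is
#'   returned when no candidate is eligible to seed.
#' @export
forward_select <- function(design, response, config = selection_config(),
                           priors = NULL) {
  stopifnot(inherits(config, "selection_config"))
  prep <- prepare_candidates(design, response, priors,
                             transform = config$response_transform)
  X <- prep$X
  y <- prep$y
  n <- nrow(X)
  if (n < 3) stopf("too few complete rows (%d) to fit anything", n)
  gram <- make_gram(X, y)
  pr <- prep$priors[gram$cols]
  prs <- vapply(pr, prior_sign, numeric(1))   # +1 / -1 / 0
  ncand <- length(gram$cols)

  new_model <- function(S, fits) {
    build_lur_model(gram, S, fits, X, y, config, pr)
  }

  # seed: top eligible univariate candidate
  r2u <- ifelse(diag(gram$G) > 0, gram$g^2 / (diag(gram$G) * gram$yy), 0)
  if (gram$yy <= 0) r2u[] <- 0
  elig <- prs == 0 | sign(gram$g) == prs
  if (!any(elig)) return(new_model(integer(0), list()))
  ord <- order(-r2u, gram$cols)
  seedj <- ord[elig[ord]][1]

  S <- seedj
  entry_r2 <- numeric(0)
  fit <- gram_fit(gram, S)
  if (is.null(fit)) return(new_model(integer(0), list()))
  entry_r2 <- fit$r2

  repeat {
    if (length(S) >= config$max_terms) break
    if (n - length(S) - 2 < 1) break           # out of residual df
    remaining <- setdiff(seq_len(ncand), S)
    if (length(remaining) == 0) break
    best <- NULL
    for (j in remaining) {
      Sj <- c(S, j)
      fj <- gram_fit(gram, Sj)
      if (is.null(fj)) next
      pj <- fj$p_values[length(Sj)]
      if (!is.finite(pj) || pj >= config$p_enter) next
      if (prs[j] != 0 && sign(fj$b[length(Sj)]) != prs[j]) next
      if (config$check_entered_signs && length(S) > 0) {
        bs <- fj$b[seq_along(S)]
        if (any(prs[S] != 0 & sign(bs) != prs[S])) next
      }
      if (any(gram_vif(gram, Sj) >= config$vif_max)) next
      gain <- fj$adj - fit$adj
      if (gain <= config$min_adj_r2_gain) next
      cand <- list(j = j, fit = fj, gain = gain, p = pj,
                   name = gram$cols[j])
      if (is.null(best) ||
          cand$gain > best$gain ||
          (cand$gain == best$gain && cand$p < best$p) ||
          (cand$gain == best$gain && cand$p == best$p &&
             cand$name < best$name)) {
        best <- cand
      }
    }
    if (is.null(best)) break
    entry_r2 <- c(entry_r2, best$fit$r2 - fit$r2)
    S <- c(S, best$j)
    fit <- best$fit
  }
  new_model(S, list(fit = fit, entry_r2 = entry_r2))
}

build_lur_model <- function(gram, S, fits, X, y, config, priors) {
  n <- gram$n
  if (length(S) == 0) {
    rmse <- sqrt(mean((y - mean(y))^2))
    terms <- data.frame(column = character(), coefficient = numeric(),
                        p_value = numeric(), incremental_r2 = numeric(),
                        sign_prior = character(), stringsAsFactors = FALSE)
    model <- list(intercept = mean(y), terms = terms, r2 = 0,
                  adjusted_r2 = 0, rmse = rmse, n_obs = n,
                  intercept_p = NA_real_,
                  response_transform = config$response_transform,
                  config = unclass(config)[c("p_enter", "vif_max",
                                             "min_adj_r2_gain", "max_terms")])
    class(model) <- "lur_model"
    return(model)
  }
  cols <- gram$cols[S]
  # definitive numbers from the plain QR fit on the original scale
  final <- fit_ols(X[, cols, drop = FALSE], y)
  terms <- data.frame(
    column = cols,
    coefficient = unname(final$coefficients[cols]),
    p_value = unname(final$p_values[cols]),
    incremental_r2 = fits$entry_r2,
    sign_prior = unname(priors[cols]),
    stringsAsFactors = FALSE
  )
  model <- list(intercept = final$intercept, terms = terms, r2 = final$r2,
                adjusted_r2 = final$adjusted_r2, rmse = final$rmse,
                n_obs = final$n_obs,
                intercept_p = unname(final$p_values["(Intercept)"]),
                response_transform = config$response_transform,
                config = unclass(config)[c("p_enter", "vif_max",
                                           "min_adj_r2_gain", "max_terms")])
  class(model) <- "lur_model"
  model
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> %d term(s), n = %d\n", nrow(x$terms), x$n_obs))
  if (nrow(x$terms) > 0) {
    print(x$terms, digits = 4)
  }
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f, RMSE = %.4g (%s response)\n",
              x$r2, x$adjusted_r2, x$rmse,
              if (x$response_transform == "log10") "log10" else "identity"))
  invisible(x)
}

#' Summary table of a fitted LUR model
#'
#' One row per term in entry order, preceded by the intercept row, with the
#' overall performance metrics attached as the `footer` attribute
#' (r2, adjusted_r2, rmse, n_obs). The result serializes byte-stably for a
#' fixed model via [write_model_csv()] / [model_to_json()].
#'
#' @param model a `lur_model`.
#' @return data frame (variable, coefficient, p_value, incremental_r2) with a
#'   `footer` attribute.
#' @export
summarize <- function(model) {
  stopifnot(inherits(model, "lur_model"))
  tab <- data.frame(
    variable = c("(Intercept)", model$terms$column),
    coefficient = c(model$intercept, model$terms$coefficient),
    p_value = c(model$intercept_p, model$terms$p_value),
    incremental_r2 = c(NA_real_, model$terms$incremental_r2),
    stringsAsFactors = FALSE
  )
  attr(tab, "footer") <- c(r2 = model$r2, adjusted_r2 = model$adjusted_r2,
                           rmse = model$rmse, n_obs = model$n_obs)
  tab
}

#' Serialize a fitted model to JSON
#'
#' Versioned, deterministic JSON serialization: identical models produce
#' identical strings.
#'
#' @param model a `lur_model`.
#' @return a JSON string (class `json`).
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "lur_model"))
  obj <- list(
    schema = "lur_model/1",
    intercept = model$intercept,
    intercept_p = model$intercept_p,
    terms = model$terms,
    r2 = model$r2, adjusted_r2 = model$adjusted_r2, rmse = model$rmse,
    n_obs = model$n_obs, response_transform = model$response_transform,
    config = model$config
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows", na = "null")
}

#' Deserialize a model written by [model_to_json()]
#'
#' @param json a JSON string or file path.
#' @return a `lur_model`.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$schema, "lur_model/1")) {
    stopf("unrecognized model schema: %s", obj$schema %||% "<none>")
  }
  terms <- as.data.frame(obj$terms, stringsAsFactors = FALSE)
  if (nrow(terms) == 0) {
    terms <- data.frame(column = character(), coefficient = numeric(),
                        p_value = numeric(), incremental_r2 = numeric(),
                        sign_prior = character(), stringsAsFactors = FALSE)
  }
  model <- list(intercept = obj$intercept, terms = terms, r2 = obj$r2,
                adjusted_r2 = obj$adjusted_r2, rmse = obj$rmse,
                n_obs = obj$n_obs,
                intercept_p = obj$intercept_p %||% NA_real_,
                response_transform = obj$response_transform,
                config = obj$config)
  class(model) <- "lur_model"
  model
}

#' Write a model summary table to CSV
#'
#' Writes the [summarize()] table followed by one metric row per overall
#' performance statistic, in a fixed format (byte-stable for a fixed model).
#'
#' @param model a `lur_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_csv <- function(model, path) {
  tab <- summarize(model)
  footer <- attr(tab, "footer")
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  lines <- c(
    "variable,coefficient,p_value,incremental_r2",
    sprintf("%s,%s,%s,%s", tab$variable, fmt(tab$coefficient),
            fmt(tab$p_value), fmt(tab$incremental_r2)),
    sprintf("%s,%s,,", names(footer), fmt(unname(footer)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Fit a LUR model with a fixed term structure
#'
#' Ordinary least squares on a prescribed set of design columns, packaged as
#' a `lur_model` (entry order = the given column order, incremental R-squared
#' computed over the sequence of prefix fits). Useful for refitting a known
#' term structure, e.g. in refit-mode validation.
#'
#' @inheritParams forward_select
#' @param columns design column names to fit, in entry order.
#' @return a `lur_model`.
#' @export
fit_lur <- function(design, response, columns, config = selection_config(),
                    priors = NULL) {
  prep <- prepare_candidates(design, response, priors,
                             transform = config$response_transform)
  missing_cols <- setdiff(columns, colnames(prep$X))
  if (length(missing_cols) > 0) {
    stopf("column(s) not in design: %s", paste(missing_cols, collapse = ", "))
  }
  X <- prep$X[, columns, drop = FALSE]
  y <- prep$y
  final <- fit_ols(X, y)
  prefix_r2 <- vapply(seq_along(columns), function(k) {
    fit_ols(X[, seq_len(k), drop = FALSE], y)$r2
  }, numeric(1))
  terms <- data.frame(
    column = columns,
    coefficient = unname(final$coefficients[columns]),
    p_value = unname(final$p_values[columns]),
    incremental_r2 = diff(c(0, prefix_r2)),
    sign_prior = unname(prep$priors[columns]),
    stringsAsFactors = FALSE
  )
  model <- list(intercept = final$intercept, terms = terms, r2 = final$r2,
                adjusted_r2 = final$adjusted_r2, rmse = final$rmse,
                n_obs = final$n_obs,
                intercept_p = unname(final$p_values["(Intercept)"]),
                response_transform = config$response_transform,
                config = unclass(config)[c("p_enter", "vif_max",
                                           "min_adj_r2_gain", "max_terms")])
  class(model) <- "lur_model"
  model
}
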