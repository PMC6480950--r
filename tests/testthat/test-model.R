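test_that("fit_ols recovers exact fits and matches the normal-equations oracle", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  f <- fit_ols(x, 2 * (1:10))
  expect_equal(unname(f$coefficients), 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-9)

  # constant response convention
  fc <- fit_ols(x, rep(7, 10))
  expect_equal(fc$r2, 0)
  expect_equal(unname(fc$coefficients), 0)
  expect_equal(fc$intercept, 7, tolerance = 1e-12)

  # fixed 12-row fixture vs longhand (X'X)^-1 X'y
  set.seed(101)
  X <- cbind(a = runif(12), b = rnorm(12), c = runif(12, 5, 9))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(12, 0, 0.3)
  f2 <- fit_ols(X, y)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(c(f2$intercept, f2$coefficients), drop(beta),
               tolerance = 1e-8, ignore_attr = TRUE)
  res <- y - Xi %*% beta
  expect_equal(f2$rmse, sqrt(mean(res^2)), tolerance = 1e-8)
  expect_equal(f2$r2, 1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(f2$adjusted_r2, 1 - (1 - f2$r2) * 11 / (12 - 3 - 1),
               tolerance = 1e-10)
  # p-values agree with lm()
  lmfit <- summary(lm(y ~ X))
  expect_equal(unname(f2$p_values), unname(lmfit$coefficients[, 4]),
               tolerance = 1e-9)
})

test_that("fit_ols names collinear columns in rank-deficient designs", {
  set.seed(7)
  X <- cbind(u = runif(20), v = runif(20))
  X <- cbind(X, w = X[, "u"] + X[, "v"])
  expect_error(fit_ols(X, rnorm(20)), "w")
})

test_that("VIF matches its closed form and flags perfect collinearity as Inf", {
  # centred orthonormal pair by Gram-Schmidt
  set.seed(42)
  a <- rnorm(20); b <- rnorm(20)
  e1 <- a - mean(a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- b - mean(b); e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  expect_equal(unname(vif(cbind(e1, e2))), c(1, 1), tolerance = 1e-9)

  # sample correlation exactly 0.8 -> VIF = 1/(1-0.64)
  x2 <- 0.8 * e1 + sqrt(1 - 0.8^2) * e2
  v <- vif(cbind(a = e1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  expect_true(all(vif(cbind(e1, e1)) == Inf))
})

test_that("univariate screening ranks by r2 and enforces sign priors", {
  set.seed(111)
  y <- rnorm(40)
  X <- cbind(self = y, anti = -y, n1 = rnorm(40), n2 = rnorm(40),
             n3 = rnorm(40))
  pri <- c(self = "positive", anti = "positive", n1 = "unconstrained",
           n2 = "negative", n3 = "positive")
  sc <- univariate_screen(X, y, pri)
  expect_equal(sc$column[1:2], c("anti", "self")) # tie broken by name
  expect_true(sc$eligible[sc$column == "self"])
  expect_false(sc$eligible[sc$column == "anti"])
  expect_equal(sc$r2[sc$column == "self"], 1, tolerance = 1e-12)

  # ranking matches per-column OLS r2
  for (cn in colnames(X)) {
    expect_equal(sc$r2[sc$column == cn],
                 fit_ols(X[, cn, drop = FALSE], y)$r2, tolerance = 1e-9)
  }
})

test_that("forward selection handles the degenerate seeding cases", {
  set.seed(121)
  y <- rnorm(50)
  X <- cbind(a = y + rnorm(50, 0, 0.1), b = 0.5 * y + rnorm(50, 0, 0.5))
  # every candidate violates its prior univariately -> intercept-only
  m0 <- forward_select(X, y, selection_config(),
                       priors = c(a = "negative", b = "negative"))
  expect_equal(nrow(m0$terms), 0)
  expect_equal(m0$intercept, mean(y), tolerance = 1e-12)
  expect_equal(m0$r2, 0)

  # a perfect predictor saturates the model and selection stops
  Xp <- cbind(exact = y, noise1 = rnorm(50), noise2 = rnorm(50))
  mp <- forward_select(Xp, y, selection_config(),
                       priors = c(exact = "positive", noise1 = "unconstrained",
                                  noise2 = "unconstrained"))
  expect_equal(mp$terms$column, "exact")
  expect_equal(mp$terms$incremental_r2, 1, tolerance = 1e-9)
  expect_equal(mp$r2, 1, tolerance = 1e-9)
})

make_selection_fixture <- function(n = 120, seed = 131) {
  set.seed(seed)
  X <- cbind(p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n), p4 = rnorm(n),
             d1 = rnorm(n), d2 = rnorm(n), d3 = rnorm(n), d4 = rnorm(n))
  y <- 2 + 1.0 * X[, "p1"] - 0.8 * X[, "p2"] + 0.5 * X[, "p3"] + rnorm(n, 0, 1)
  pri <- c(p1 = "positive", p2 = "negative", p3 = "positive",
           p4 = "positive", d1 = "unconstrained", d2 = "unconstrained",
           d3 = "negative", d4 = "unconstrained")
  list(X = X, y = y, priors = pri)
}

test_that("selection obeys its own admission invariants", {
  fx <- make_selection_fixture()
  m <- forward_select(fx$X, fx$y, selection_config(), priors = fx$priors)
  expect_gte(nrow(m$terms), 2)

  # constrained signs respected
  constrained <- m$terms$sign_prior != "unconstrained"
  expect_true(all(sign(m$terms$coefficient[constrained]) ==
                    ifelse(m$terms$sign_prior[constrained] == "positive", 1, -1)))
  # all VIF below the gate
  if (nrow(m$terms) >= 2) {
    expect_true(all(vif(fx$X[, m$terms$column]) < 3))
  }
  # incremental r2 telescopes to the final r2
  expect_true(all(m$terms$incremental_r2 >= 0))
  expect_equal(sum(m$terms$incremental_r2), m$r2, tolerance = 1e-9)
  # adjusted r2 strictly increases along the entry sequence
  adj <- vapply(seq_len(nrow(m$terms)), function(k) {
    fit_ols(fx$X[, m$terms$column[seq_len(k)], drop = FALSE], fx$y)$adjusted_r2
  }, numeric(1))
  expect_true(all(diff(c(0, adj)) > 0))
})

test_that("selection is deterministic and monotone in the p-value gate", {
  fx <- make_selection_fixture()
  m1 <- forward_select(fx$X, fx$y, selection_config(), priors = fx$priors)
  m2 <- forward_select(fx$X, fx$y, selection_config(), priors = fx$priors)
  expect_identical(as.character(model_to_json(m1)),
                   as.character(model_to_json(m2)))

  gates <- c(0.001, 0.01, 0.05, 0.1, 0.3)
  sets <- lapply(gates, function(pe) {
    forward_select(fx$X, fx$y, selection_config(p_enter = pe),
                   priors = fx$priors)$terms$column
  })
  for (i in seq_len(length(gates) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("max_terms and the log10 transform are honoured", {
  fx <- make_selection_fixture()
  m1 <- forward_select(fx$X, fx$y, selection_config(max_terms = 1),
                       priors = fx$priors)
  expect_equal(nrow(m1$terms), 1)

  ylog <- 10^(fx$y / 10)  # strictly positive response
  ml <- forward_select(fx$X, ylog,
                       selection_config(response_transform = "log10"),
                       priors = fx$priors)
  expect_equal(ml$response_transform, "log10")
  pred <- predict_at_points(ml, as.data.frame(fx$X))
  # back-transformed predictions live on the response scale
  expect_true(all(pred > 0))
  expect_equal(ml$r2,
               fit_ols(fx$X[, ml$terms$column, drop = FALSE], log10(ylog))$r2,
               tolerance = 1e-9)
})

test_that("model summaries conserve r2 and serialize byte-stably", {
  fx <- make_selection_fixture()
  m <- forward_select(fx$X, fx$y, selection_config(), priors = fx$priors)
  tab <- summarize(m)
  expect_equal(tab$variable[1], "(Intercept)")
  expect_equal(tab$variable[-1], m$terms$column)
  expect_equal(sum(tab$incremental_r2, na.rm = TRUE), m$r2, tolerance = 1e-9)
  foot <- attr(tab, "footer")
  expect_equal(unname(foot["adjusted_r2"]), m$adjusted_r2)

  # serialize -> parse -> serialize is the identity on bytes
  j1 <- as.character(model_to_json(m))
  j2 <- as.character(model_to_json(model_from_json(j1)))
  expect_identical(j1, j2)

  # CSV write is byte-stable
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_model_csv(m, p1); write_model_csv(m, p2)
  expect_identical(readLines(p1), readLines(p2))

  # intercept-only model still summarizes
  set.seed(141)
  y0 <- rnorm(30)
  X0 <- cbind(a = y0 + rnorm(30, 0, 0.1), b = 0.7 * y0 + rnorm(30, 0, 0.2))
  m0 <- forward_select(X0, y0, selection_config(),
                       priors = c(a = "negative", b = "negative"))
  expect_equal(nrow(m0$terms), 0)
  expect_equal(nrow(summarize(m0)), 1)
})
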