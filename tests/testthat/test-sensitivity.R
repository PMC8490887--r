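# Monte-Carlo sampling and the sensitivity statistics.

test_that("sampling is reproducible, ranged, and degenerate at [1,1]", {
  d <- sensitivity_design(n = 100, seed = 9)
  m1 <- sample_parameters(d)
  m2 <- sample_parameters(d)
  expect_identical(m1, m2)
  expect_equal(ncol(m1), 18)

  base <- adm1_params()
  for (nm in colnames(m1)) {
    mult <- m1[, nm] / base[[nm]]
    rng <- if (grepl("^K_S", nm)) c(0.1, 10) else c(0.5, 1.5)
    expect_true(all(mult >= rng[1] & mult <= rng[2]))
  }

  dd <- sensitivity_design(n = 50, seed = 9, rate_range = c(1, 1),
                           ks_range = c(1, 1))
  md <- sample_parameters(dd)
  expect_true(all(apply(md, 1, function(r)
    all(r == unlist(base[colnames(md)])))))
})

test_that("a large uniform sample recovers the default as its mean", {
  d <- sensitivity_design(n = 1e5, seed = 4, parameters = "k_m_ac")
  m <- sample_parameters(d)
  expect_equal(mean(m[, "k_m_ac"]), adm1_params()$k_m_ac, tolerance = 0.01)
})

test_that("partial correlation matches the double-regression oracle", {
  set.seed(31)
  X <- matrix(stats::rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- stats::rnorm(6)
  pcc <- partial_correlation(X, y)
  for (j in 1:3) {
    rx <- stats::residuals(stats::lm(X[, j] ~ X[, -j]))
    ry <- stats::residuals(stats::lm(y ~ X[, -j]))
    expect_equal(pcc[[j]], stats::cor(rx, ry), tolerance = 1e-10)
  }
  expect_true(all(abs(pcc) <= 1))
})

test_that("PCC is 1 for an exact driver and ~0 under the null", {
  set.seed(32)
  n <- 400
  X <- matrix(stats::rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1]
  pcc <- partial_correlation(X, y)
  expect_equal(pcc[["a"]], 1, tolerance = 1e-8)

  y0 <- stats::rnorm(n)   # independent of X
  pcc0 <- partial_correlation(X, y0)
  expect_true(all(abs(pcc0) < 3 / sqrt(n)))
})

test_that("standardized regression matches the normal equations and its limits", {
  set.seed(33)
  n <- 500
  X <- matrix(stats::rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + stats::rnorm(n, 0, 0.3)
  src <- standardized_regression(X, y)
  # normal-equations oracle on z-scores
  Z <- scale(X); zy <- scale(y)
  beta <- solve(crossprod(Z), crossprod(Z, zy))
  expect_equal(unname(src), unname(drop(beta)), tolerance = 1e-10)
  # orthogonal columns: SRC approx Pearson correlation
  expect_equal(src[["a"]], stats::cor(X[, 1], y), tolerance = 0.02)

  expect_equal(unname(standardized_regression(X, rep(5, n))), rep(0, 3))
  Xbad <- cbind(X, d = X[, 1])
  expect_error(partial_correlation(Xbad, y), "degenerate")
})

test_that("PCC, SRC and correlation agree on an independent linear model", {
  set.seed(34)
  n <- 2000
  X <- matrix(stats::rnorm(4 * n), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- 1.0 * X[, 1] - 0.5 * X[, 2] + 0.25 * X[, 3] + stats::rnorm(n, 0, 0.5)
  pcc <- partial_correlation(X, y)
  src <- standardized_regression(X, y)
  corr <- as.numeric(stats::cor(X, y))
  # same sign everywhere and comparable magnitude ordering
  expect_equal(sign(pcc[1:3]), sign(src[1:3]), ignore_attr = TRUE)
  expect_equal(order(-abs(src)), order(-abs(corr)))
  expect_equal(unname(src), corr, tolerance = 0.06)
})

test_that("the statistics are invariant to affine rescaling of a parameter", {
  set.seed(35)
  n <- 300
  X <- matrix(stats::rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5) + stats::rnorm(n, 0, 0.2)
  X2 <- X; X2[, 2] <- 1000 * X2[, 2] + 7
  expect_equal(partial_correlation(X, y), partial_correlation(X2, y),
               tolerance = 1e-9)
  expect_equal(standardized_regression(X, y), standardized_regression(X2, y),
               tolerance = 1e-9)
})

test_that("rank-transformed variants capture monotone nonlinear drivers", {
  set.seed(36)
  n <- 400
  X <- matrix(stats::runif(3 * n, -2, 2), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- exp(2 * X[, 1]) + stats::rnorm(n, 0, 0.05)
  prcc <- partial_correlation(X, y, rank = TRUE)
  pcc <- partial_correlation(X, y)
  expect_gt(prcc[["a"]], 0.99)               # monotone: near-perfect on ranks
  expect_gt(prcc[["a"]], pcc[["a"]])         # and stronger than the raw PCC
  srrc <- standardized_regression(X, y, rank = TRUE)
  expect_gt(srrc[["a"]], 0.95)
})

test_that("selection ranks by max |statistic|, breaks ties by name", {
  res <- data.frame(
    parameter = rep(c("k_m_ac", "k_m_pro", "K_S_h2"), each = 2),
    output = rep(c("COD_eff", "Q_gas"), 3),
    pcc = c(0.9, -0.2, 0.1, 0.05, -0.9, 0.3),
    src = 0, corr = 0)
  sel <- select_sensitive(res, n_select = 1)
  expect_equal(unname(sel), "K_S_h2", ignore_attr = TRUE)   # tie with k_m_ac at 0.9 -> lexicographic
  sel2 <- select_sensitive(res, n_select = 2)
  expect_setequal(sel2, c("k_m_ac", "K_S_h2"))

  one <- data.frame(parameter = c("x", "y"), output = "COD_eff",
                    pcc = c(0.99, 0.01), src = 0, corr = 0)
  expect_equal(unname(select_sensitive(one, n_select = 1)), "x", ignore_attr = TRUE)
})

test_that("a model driven only by the six sensitive kinetics selects exactly them", {
  # constructed ground truth: outputs respond linearly to the six
  # propionate/acetate/hydrogen constants and to nothing else
  d <- sensitivity_design(n = 300, seed = 12)
  m <- sample_parameters(d)
  Z <- scale(log(m))
  six <- sensitive_param_names()
  set.seed(13)
  cod <- Z[, "k_m_pro"] - 0.8 * Z[, "K_S_pro"] + 0.9 * Z[, "k_m_ac"] -
    0.7 * Z[, "K_S_ac"] + 0.8 * Z[, "k_m_h2"] - 0.6 * Z[, "K_S_h2"] +
    stats::rnorm(300, 0, 0.1)
  gas <- -0.9 * Z[, "k_m_ac"] + 0.6 * Z[, "K_S_ac"] + 0.5 * Z[, "k_m_pro"] +
    stats::rnorm(300, 0, 0.1)
  res <- sensitivity_result(m, data.frame(COD_eff = cod, Q_gas = gas))
  expect_setequal(unname(select_sensitive(res, n_select = 6)), six)
})

test_that("identical parameter sets give identical ensemble rows", {
  base <- adm1_params("estimated")
  m <- do.call(rbind, rep(list(unlist(base[sensitive_param_names()])), 3))
  colnames(m) <- sensitive_param_names()
  ser <- constant_influent_series(table1_influent(), 12)
  out <- run_ensemble(m, ser, base_params = base, window = 5)
  expect_equal(out[1, ], out[2, ], ignore_attr = TRUE)
  expect_equal(out[1, ], out[3, ], ignore_attr = TRUE)
  expect_true(all(is.finite(unlist(out))))
})

test_that("parameters unrelated to the inert leave effluent S_I unchanged", {
  # in a biomass-free plant no sampled kinetic constant can touch S_I
  inf <- table1_influent()
  cfg <- plant_config()
  ser <- constant_influent_series(inf, 15)
  y0 <- initial_plant_state(inf, cfg, adm1_params(), seed_biomass = 0)
  r1 <- simulate_plant(ser, params = adm1_params(), init = y0)
  r2 <- simulate_plant(ser, params = adm1_params(c(k_m_ac = 4.0,
                                                   k_m_pro = 7.5)),
                       init = y0)
  expect_equal(r1$S_I_eff, r2$S_I_eff, tolerance = 1e-12)
})
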