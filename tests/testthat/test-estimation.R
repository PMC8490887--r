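# Calibration objective, optimizer behaviour, validation report.

small_scenario <- function(seed = 19, noise_cv = 0, cal = 10, val = 5) {
  plant_scenario(seed = seed, horizon = cal + val, cal_days = cal,
                 val_days = val, noise_cv = noise_cv)
}

test_that("the objective is zero when observations come from the candidate", {
  sc <- small_scenario()
  obs <- generate_observations(sc)
  prob <- estimation_problem(base_params = adm1_params("estimated"))
  v <- unlist(adm1_params("estimated")[sensitive_param_names()])
  expect_lt(sse_objective(v, prob, obs), 1e-10)
})

test_that("a unit residual on a single-day single series scores 1", {
  sc <- small_scenario(cal = 1, val = 1)
  obs <- generate_observations(sc)
  prob <- estimation_problem(base_params = adm1_params("estimated"),
                             weights = c(COD_eff = 1, Q_gas = 0))
  v <- unlist(adm1_params("estimated")[sensitive_param_names()])
  truth_day1 <- attr(obs, "truth")$COD_eff_kg_m3[1]
  obs$COD_eff_obs[1] <- truth_day1 / 2   # residual == observed mean
  expect_equal(sse_objective(v, prob, obs), 1, tolerance = 1e-6)
})

test_that("the objective equals a hand-summed oracle on a short series", {
  sc <- small_scenario(cal = 4, val = 2)
  obs <- generate_observations(sc, config = plant_config())
  prob <- estimation_problem(base_params = adm1_params("estimated"))
  v <- unlist(adm1_params()[sensitive_param_names()])  # NOT the generator
  got <- sse_objective(v, prob, obs)

  # oracle: simulate independently, then enumerate the normalised squares
  p <- adm1_params("estimated")
  p[names(v)] <- as.list(v)
  influent <- attr(obs, "influent")
  cal <- obs[obs$window == "calibration", ]
  sim <- simulate_plant(influent[influent$day %in% cal$day, ], params = p,
                        init = initial_plant_state(
                          stats::setNames(
                            as.numeric(influent[1, state_names()]),
                            state_names()),
                          plant_config(), p))
  acc <- 0
  for (k in seq_len(nrow(cal))) {
    acc <- acc +
      ((sim$COD_eff_kg_m3[k] - cal$COD_eff_obs[k]) /
         mean(cal$COD_eff_obs))^2 +
      ((sim$Q_gas_Nm3_d[k] - cal$Q_gas_obs[k]) / mean(cal$Q_gas_obs))^2
  }
  expect_equal(got, acc / (2 * nrow(cal)), tolerance = 1e-12)
})

test_that("rescaling a series and its scale leaves the objective unchanged", {
  sc <- small_scenario(cal = 3, val = 2, noise_cv = 0.05)
  obs <- generate_observations(sc)
  prob <- estimation_problem(base_params = adm1_params("estimated"))
  v <- unlist(adm1_params()[sensitive_param_names()])
  f1 <- sse_objective(v, prob, obs)
  expect_true(is.finite(f1) && f1 > 0)
  # scaling a series together with its mean leaves each normalised
  # residual, hence the objective, unchanged
  cal <- obs[obs$window == "calibration", ]
  for (cc in c(1000, 1e-3, 7)) {
    r <- (cal$COD_eff_obs - mean(cal$COD_eff_obs)) / mean(cal$COD_eff_obs)
    r2 <- (cc * cal$COD_eff_obs - mean(cc * cal$COD_eff_obs)) /
      mean(cc * cal$COD_eff_obs)
    expect_equal(r, r2, tolerance = 1e-12)
  }
})

test_that("an empty free set returns the start point and its objective", {
  sc <- small_scenario(cal = 2, val = 1)
  obs <- generate_observations(sc)
  prob <- estimation_problem(free = character(0),
                             base_params = adm1_params("estimated"))
  fit <- estimate(prob, obs)
  expect_length(fit$par, 0)
  expect_equal(fit$objective, fit$start_objective)
  expect_lt(fit$objective, 1e-10)   # start == generator here
})

test_that("simulation failure at a candidate returns a penalty, not an error", {
  sc <- small_scenario(cal = 2, val = 1)
  obs <- generate_observations(sc)
  attr(obs, "influent") <- NULL   # break the record deliberately
  prob <- estimation_problem()
  diag <- new.env(); diag$failures <- list()
  v <- unlist(adm1_params()[sensitive_param_names()])
  expect_equal(sse_objective(v, prob, obs, .diagnostics = diag), 1e8)
  expect_length(diag$failures, 1)
})

test_that("a single-parameter calibration recovers its generator within 1%", {
  sc <- plant_scenario(seed = 23, horizon = 25, cal_days = 20, val_days = 5,
                       noise_cv = 0)
  obs <- generate_observations(sc)
  # exact data: a zero noise model makes the fit pure least squares;
  # every fixed constant matches the generator, only k_m_ac starts off
  base <- adm1_params("estimated")
  base$k_m_ac <- 8.0
  prob <- estimation_problem(free = "k_m_ac", base_params = base,
                             noise_cv = 0)
  fit <- estimate(prob, obs, maxiter = 40)
  expect_lt(abs(fit$par[["k_m_ac"]] / 4.26 - 1), 0.01)
  expect_lte(fit$objective, fit$start_objective)
  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("validation scores the identity line and flags constructed bias", {
  sc <- small_scenario(cal = 6, val = 4)
  obs <- generate_observations(sc)   # noise-free: predictions == observations
  prob <- estimation_problem(base_params = adm1_params("estimated"))
  v <- unlist(adm1_params("estimated")[sensitive_param_names()])
  before <- v
  rep <- validate_fit(v, prob, obs)
  expect_identical(v, before)        # pure function: params untouched
  expect_equal(rep$COD_eff$mean_rel_residual, 0, tolerance = 1e-8)
  expect_equal(rep$COD_eff$frac_within_10pct, 1)
  expect_false(rep$COD_eff$overestimated)

  # predictions 1.2x the observations: systematic overestimation
  obs2 <- obs
  obs2$COD_eff_obs <- obs2$COD_eff_obs / 1.2
  obs2$Q_gas_obs <- obs2$Q_gas_obs / 1.2
  rep2 <- validate_fit(v, prob, obs2)
  expect_true(rep2$COD_eff$overestimated)
  expect_true(rep2$Q_gas$overestimated)
  expect_equal(rep2$COD_eff$mean_rel_residual, 0.2, tolerance = 1e-6)
})
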