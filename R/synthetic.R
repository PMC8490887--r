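# Synthetic plant records: the study's field time series are not public,
# so calibration/validation/sensitivity are exercised on series generated
# with the statistical structure the analysis assumes (roughly stationary
# influent, daily observations, multiplicative measurement noise).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for any stochastic draw")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.ar1 <- function(n, mean, sd, rho) {
  if (sd <= 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mean, sd)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) x[t] <- mean + rho * (x[t - 1] - mean) + innov[t]
  x
}

#' The plant influent assay (means and day-to-day SDs)
#'
#' The routine characterisation of the deinking-pulp wastewater entering
#' the anaerobic section, in g COD m^-3: total COD 934.98 +/- 63.29,
#' soluble COD 862.84 +/- 72.99, with monosaccharide, VFA (as acetic
#' acid), anionic-surfactant (as stearate) and inert-soluble fractions.
#' The suspended-solids COD is the TCOD-SCOD difference (72.14).
#'
#' @return A [wastewater_assay()] with an `sd` component.
#' @export
fixture_table1 <- function() {
  wastewater_assay(
    tcod = 934.98, scod = 862.84, cod_su = 425.14, cod_ac = 197.82,
    cod_li = 51.77, cod_sI = 197.87,
    sd = c(tcod = 63.29, scod = 72.99, cod_su = 65.47, cod_ac = 42.89,
           cod_li = 14.71, cod_sI = 19.47, sscod = 19.71))
}

#' A synthetic plant scenario
#'
#' Bundles everything the generator needs: horizon and
#' calibration/validation split, the influent assay statistics, the flow
#' profile (default 4500 m^3 d^-1, giving tank/reactor HRTs of 4 h/8 h),
#' the generating parameter set (default: the field-calibrated set), the
#' observation noise model, and the seed (mandatory).
#'
#' @param seed integer seed; every stochastic draw is a pure function of
#'   (scenario, seed).
#' @param horizon days (calibration + validation must sum to it).
#' @param cal_days,val_days window split.
#' @param assay influent assay with `sd`, default [fixture_table1()].
#' @param ar1_rho day-to-day autocorrelation of every influent channel.
#' @param flow_mean,flow_cv,flow_rho inflow profile (m^3 d^-1).
#' @param params generating parameter set.
#' @param noise_cv multiplicative lognormal observation noise CV applied
#'   independently per day and channel.
#' @param S_IN,S_IC,S_cat,S_an influent inorganic/ion defaults
#'   (kmol m^-3), passed to [fractionate()].
#' @param seed_biomass initial biomass per trophic group (kgCOD m^-3).
#' @return Named list (`SyntheticPlantScenario`).
#' @export
plant_scenario <- function(seed, horizon = 250, cal_days = 150,
                           val_days = 100, assay = fixture_table1(),
                           ar1_rho = 0.7, flow_mean = 4500,
                           flow_cv = 0.05, flow_rho = 0.7,
                           params = adm1_params("estimated"),
                           noise_cv = 0.05,
                           S_IN = 0.01, S_IC = 0.03, S_cat = 0.04,
                           S_an = 0.02, seed_biomass = 0.5) {
  stopifnot(cal_days + val_days == horizon, horizon >= 1,
            all(assay$sd >= 0), noise_cv >= 0)
  if (missing(seed)) stop("a seed is mandatory")
  list(seed = as.integer(seed), horizon = horizon, cal_days = cal_days,
       val_days = val_days, assay = assay, ar1_rho = ar1_rho,
       flow_mean = flow_mean, flow_cv = flow_cv, flow_rho = flow_rho,
       params = params, noise_cv = noise_cv,
       S_IN = S_IN, S_IC = S_IC, S_cat = S_cat, S_an = S_an,
       seed_biomass = seed_biomass)
}

#' Generate a daily influent series
#'
#' Each assay channel follows a first-order autoregressive process around
#' its mean with stationary SD equal to the assay SD, truncated at zero.
#' `SCOD <= TCOD` holds by construction: TCOD and the suspended-solids
#' COD are drawn jointly and SCOD is their difference. The daily assays
#' are fractionated into ADM1 influent states with the scenario's
#' inorganic defaults.
#'
#' @param scenario [plant_scenario()].
#' @param horizon optional override of the scenario horizon (e.g. long
#'   series for moment checks).
#' @return Data frame: `day`, `Q_inf`, the assay channels (`tcod`,
#'   `scod`, ...) and the 26 influent state columns.
#' @export
generate_influent_series <- function(scenario, horizon = scenario$horizon) {
  a <- scenario$assay
  sd <- a$sd
  rho <- scenario$ar1_rho
  .with_seed(scenario$seed, {
    n <- horizon
    tcod <- pmax(.ar1(n, a$tcod, sd[["tcod"]], rho), 0)
    sscod <- pmax(.ar1(n, a$tcod - a$scod, sd[["sscod"]], rho), 0)
    sscod <- pmin(sscod, tcod)
    scod <- tcod - sscod
    ac <- pmax(.ar1(n, a$cod_ac, sd[["cod_ac"]], rho), 0)
    li <- pmax(.ar1(n, a$cod_li, sd[["cod_li"]], rho), 0)
    sI <- pmax(.ar1(n, a$cod_sI, sd[["cod_sI"]], rho), 0)
    # keep the named non-carbohydrate fractions within SCOD
    over <- (ac + li + sI) / pmax(scod, 1e-9)
    shrink <- ifelse(over > 0.95, 0.95 / over, 1)
    ac <- ac * shrink; li <- li * shrink; sI <- sI * shrink
    su <- scod - ac - li - sI
    Q <- pmax(.ar1(n, scenario$flow_mean,
                   scenario$flow_cv * scenario$flow_mean,
                   scenario$flow_rho), scenario$flow_mean * 0.1)
    df <- data.frame(day = seq_len(n), Q_inf = Q, tcod = tcod, scod = scod,
                     cod_su = su, cod_ac = ac, cod_li = li, cod_sI = sI)
    states <- t(vapply(seq_len(n), function(k) {
      fractionate(
        wastewater_assay(tcod[k], scod[k], su[k], ac[k], li[k], sI[k]),
        S_IN = scenario$S_IN, S_IC = scenario$S_IC,
        S_cat = scenario$S_cat, S_an = scenario$S_an)
    }, numeric(26)))
    cbind(df, as.data.frame(states))
  })
}

#' Generate a synthetic observation series
#'
#' Simulates the plant on a generated influent record under the
#' scenario's parameter set, then applies independent multiplicative
#' lognormal noise (mean-unbiased) to the daily effluent COD and biogas
#' flow. Calibration/validation window labels are attached, and the
#' influent series and noise-free truth ride along as attributes
#' `"influent"` and `"truth"` so that calibration re-simulates the same
#' forcing.
#'
#' @param scenario [plant_scenario()].
#' @param config plant configuration.
#' @return `ObservationSeries` data frame: `day`, `COD_eff_obs`,
#'   `Q_gas_obs`, `COD_preacid_obs`, `window`.
#' @export
generate_observations <- function(scenario, config = plant_config()) {
  influent <- generate_influent_series(scenario)
  truth <- simulate_plant(influent, params = scenario$params,
                          config = config,
                          init = initial_plant_state(
                            stats::setNames(
                              as.numeric(influent[1, state_names()]),
                              state_names()),
                            config, scenario$params,
                            scenario$seed_biomass))
  n <- nrow(truth)
  noisy <- .with_seed(scenario$seed + 1L, {
    cv <- scenario$noise_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      f1 <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
      f2 <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
      f3 <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    } else {
      f1 <- f2 <- f3 <- rep(1, n)
    }
    data.frame(
      day = truth$day,
      COD_eff_obs = truth$COD_eff_kg_m3 * f1,
      Q_gas_obs = truth$Q_gas_Nm3_d * f2,
      COD_preacid_obs = truth$COD_preacid_kg_m3 * f3,
      window = c(rep("calibration", scenario$cal_days),
                 rep("validation", scenario$val_days))[seq_len(n)])
  })
  if (any(!noisy$day[-1] > noisy$day[-n])) stop("days must be increasing")
  attr(noisy, "influent") <- influent
  attr(noisy, "truth") <- truth
  attr(noisy, "scenario_seed") <- scenario$seed
  noisy
}
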