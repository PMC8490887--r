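# Monte-Carlo global sensitivity of the 18 kinetic parameters against the
# plant's two operating indicators (effluent COD, biogas flow), reported
# as partial correlation, standardized regression and Pearson correlation.

#' A Monte-Carlo sample design over the 18 kinetic parameters
#'
#' Sampling is independent per parameter, as a multiplier of its default:
#' uniform on `[0.5, 1.5]` for the rate constants (first-order constants
#' and Monod maxima) and log-uniform on `[0.1, 10]` for the
#' half-saturation constants, whose plausible ranges span decades. The
#' ranges are declared configuration, not field claims.
#'
#' @param n sample count (default 500); must be at least the number of
#'   parameters + 2.
#' @param seed integer seed.
#' @param parameters parameter names (default the analysed 18).
#' @param rate_range,ks_range multiplier ranges.
#' @return Named list (`SampleDesign`) with a per-parameter `dist` table.
#' @export
sensitivity_design <- function(n = 500, seed = 1,
                               parameters = kinetic_param_names(),
                               rate_range = c(0.5, 1.5),
                               ks_range = c(0.1, 10)) {
  if (n < length(parameters) + 2)
    stop("sample count must be at least number of parameters + 2")
  stopifnot(all(rate_range > 0), all(ks_range > 0))
  is_ks <- grepl("^K_S", parameters)
  tab <- data.frame(
    parameter = parameters,
    dist = ifelse(is_ks, "logunif", "unif"),
    lo = ifelse(is_ks, ks_range[1], rate_range[1]),
    hi = ifelse(is_ks, ks_range[2], rate_range[2]))
  list(n = as.integer(n), seed = as.integer(seed), table = tab)
}

#' Draw the Monte-Carlo parameter matrix
#'
#' @param design [sensitivity_design()].
#' @param base_params defaults the multipliers apply to.
#' @return n x p numeric matrix of absolute parameter values (columns
#'   named by parameter); reproducible given the design seed.
#' @export
sample_parameters <- function(design, base_params = adm1_params()) {
  tab <- design$table
  .with_seed(design$seed, {
    cols <- lapply(seq_len(nrow(tab)), function(j) {
      base <- base_params[[tab$parameter[j]]]
      if (tab$dist[j] == "logunif")
        base * exp(stats::runif(design$n, log(tab$lo[j]), log(tab$hi[j])))
      else
        base * stats::runif(design$n, tab$lo[j], tab$hi[j])
    })
    m <- do.call(cbind, cols)
    colnames(m) <- tab$parameter
    m
  })
}

#' Run the simulation ensemble
#'
#' One plant simulation per sampled parameter set; the scalar outputs are
#' the means of effluent COD and biogas flow over the last `window` days
#' of the run. Failed runs are recorded as `NA` rows with their
#' diagnostics kept, never silently dropped; more than 10% failures
#' raises a design warning.
#'
#' @param samples matrix from [sample_parameters()].
#' @param influent_series influent record (see [simulate_plant()]).
#' @param config plant configuration.
#' @param base_params defaults for the unsampled parameters.
#' @param window steady-window length in days (default 30).
#' @return Data frame `COD_eff`, `Q_gas`, one row per sample, with
#'   attribute `"failures"` (list of solver diagnostics).
#' @export
run_ensemble <- function(samples, influent_series, config = plant_config(),
                         base_params = adm1_params(), window = 30) {
  n <- nrow(samples)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("COD_eff", "Q_gas")))
  failures <- list()
  for (k in seq_len(n)) {
    p <- base_params
    p[colnames(samples)] <- as.list(samples[k, ])
    res <- tryCatch(
      simulate_plant(influent_series, params = p, config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(sample = k,
                                                message = conditionMessage(res))
    } else {
      tailrows <- utils::tail(seq_len(nrow(res)), window)
      out[k, ] <- c(mean(res$COD_eff_kg_m3[tailrows]),
                    mean(res$Q_gas_Nm3_d[tailrows]))
    }
  }
  if (length(failures) > n / 10)
    warning(sprintf("ensemble design warning: %d of %d runs failed",
                    length(failures), n))
  res <- as.data.frame(out)
  attr(res, "failures") <- failures
  res
}

.check_design_matrix <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (qr(cbind(1, scale(X, scale = FALSE)))$rank < ncol(X) + 1)
    stop("degenerate sample matrix: columns are rank deficient")
  X
}

.rank_transform <- function(X, y) {
  list(X = apply(as.matrix(X), 2, rank), y = rank(y))
}

#' Partial correlation of each column with an output
#'
#' The correlation between the residuals of `x_j` and of `y` after each
#' is regressed (with intercept) on all other columns — the
#' double-regression definition. With `rank = TRUE` inputs and output
#' are rank-transformed first, giving the partial rank correlation
#' (PRCC), robust to monotone nonlinearity.
#'
#' @param X sample matrix (columns = parameters).
#' @param y output vector.
#' @param rank rank-transform before computing (PRCC / SRRC variant).
#' @return Named vector of partial correlation coefficients in [-1, 1].
#' @export
partial_correlation <- function(X, y, rank = FALSE) {
  if (rank) {
    r <- .rank_transform(X, y)
    X <- r$X; y <- r$y
  }
  X <- .check_design_matrix(X, y)
  p <- ncol(X)
  out <- numeric(p)
  for (j in seq_len(p)) {
    Z <- cbind(1, X[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, X[, j])$residuals
    ry <- stats::lm.fit(Z, y)$residuals
    out[j] <- if (stats::sd(rx) == 0 || stats::sd(ry) == 0) 0
              else stats::cor(rx, ry)
  }
  stats::setNames(out, colnames(X))
}

#' Standardized regression coefficients
#'
#' Least-squares coefficients of the z-scored output on the z-scored
#' columns; for uncorrelated columns these approach the Pearson
#' correlations. A constant output yields all-zero coefficients.
#'
#' @inheritParams partial_correlation
#' @return Named coefficient vector.
#' @export
standardized_regression <- function(X, y, rank = FALSE) {
  if (rank) {
    r <- .rank_transform(X, y)
    X <- r$X; y <- r$y
  }
  X <- .check_design_matrix(X, y)
  if (stats::sd(y) == 0)
    return(stats::setNames(numeric(ncol(X)), colnames(X)))
  Zx <- scale(X)
  Zy <- as.numeric(scale(y))
  stats::setNames(stats::lm.fit(cbind(1, Zx), Zy)$coefficients[-1],
                  colnames(X))
}

#' Assemble the sensitivity result table
#'
#' @param samples parameter matrix.
#' @param outputs data frame from [run_ensemble()] (`NA` rows dropped,
#'   with a note).
#' @return `SensitivityResult` data frame: `parameter`, `output`, `pcc`,
#'   `src`, `corr`.
#' @export
sensitivity_result <- function(samples, outputs) {
  ok <- stats::complete.cases(outputs)
  samples <- samples[ok, , drop = FALSE]
  res <- do.call(rbind, lapply(names(outputs), function(out_nm) {
    y <- outputs[[out_nm]][ok]
    data.frame(parameter = colnames(samples), output = out_nm,
               pcc = partial_correlation(samples, y),
               src = standardized_regression(samples, y),
               corr = as.numeric(stats::cor(samples, y)),
               row.names = NULL)
  }))
  stopifnot(all(abs(res$pcc) <= 1 + 1e-8), all(abs(res$corr) <= 1 + 1e-8))
  res
}

#' Select the sensitive parameters
#'
#' Deterministic ranked selection: each parameter is scored by its
#' largest absolute statistic across the outputs, ranked descending, ties
#' broken lexicographically by parameter name, and the top `n_select`
#' returned (in canonical parameter order).
#'
#' @param result [sensitivity_result()] table.
#' @param n_select how many parameters to keep (default 6).
#' @param statistic which column to rank on (default `"pcc"`).
#' @return Character vector of selected parameter names, with the rule
#'   recorded in attribute `"rule"`.
#' @export
select_sensitive <- function(result, n_select = 6, statistic = "pcc") {
  score <- tapply(abs(result[[statistic]]), result$parameter, max)
  ord <- order(-score, names(score), method = "radix")
  sel <- names(score)[ord][seq_len(min(n_select, length(score)))]
  sel <- sel[order(match(sel, unique(result$parameter)))]
  attr(sel, "rule") <- sprintf(
    "top %d by max |%s| across outputs; lexicographic tiebreak",
    n_select, statistic)
  sel
}
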