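#' Configuration of the synthetic fire-climate data generator
#'
#' Describes a monthly data-generating process with known statistical
#' structure: a set of climatic regressors that are either stationary AR(1)
#' (integration order 0) or random walks (order 1), each with an additive
#' sinusoidal seasonal cycle of period 12, plus a response (log area burned)
#' tied to the regressors through an error-correction recursion
#' \deqn{\Delta y_t = \alpha_0 + s\,(y_{t-1} - \sum_j \theta_j x_{j,t-1}) + \varepsilon_t}
#' with adjustment speed \eqn{s \in (-1, 0)} and long-run multipliers
#' \eqn{\theta_j}. All variables are generated directly on the log scale.
#'
#' @param n_months number of monthly observations (>= 24).
#' @param variable_specs data.frame with columns `name`, `order` (0 or 1),
#'   `seasonal_amplitude` (>= 0), `innovation_sd` (> 0), `ar` (AR(1)
#'   coefficient in (-1, 1), used only for order-0 variables) and optionally
#'   `drift` (per-month drift of order-1 variables, default 0).
#' @param cointegration_vector named numeric vector of long-run multipliers
#'   \eqn{\theta_j}; names must be a subset of `variable_specs$name`.
#'   Regressors not named get multiplier 0.
#' @param adjustment_speed error-correction coefficient, strictly inside
#'   (-1, 0) so the recursion is stable.
#' @param response_innovation_sd standard deviation of the response
#'   innovations (>= 0; 0 gives the deterministic recursion).
#' @param intercept constant term of the recursion.
#' @param response_name column name of the generated response.
#' @param start_month first month, `"YYYY-MM"`.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   configuration.
#' @return object of class `dgp_config` (a validated list).
#' @seealso [generate_regressors()], [generate_response()],
#'   [simulate_fire_panel()], [xilingol_dgp_config()]
#' @export
dgp_config <- function(n_months,
                       variable_specs,
                       cointegration_vector,
                       adjustment_speed,
                       response_innovation_sd,
                       intercept = 0,
                       response_name = "area_burned",
                       start_month = "2001-01",
                       seed = 1L) {
  variable_specs <- as.data.frame(variable_specs)
  req <- c("name", "order", "seasonal_amplitude", "innovation_sd", "ar")
  miss <- setdiff(req, names(variable_specs))
  if (length(miss))
    stop("variable_specs is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(variable_specs$drift)) variable_specs$drift <- 0
  if (anyDuplicated(variable_specs$name))
    stop("duplicated regressor names in variable_specs", call. = FALSE)
  if (!all(variable_specs$order %in% c(0, 1)))
    stop("integration order must be 0 or 1", call. = FALSE)
  if (any(variable_specs$innovation_sd <= 0))
    stop("innovation_sd must be strictly positive", call. = FALSE)
  if (any(variable_specs$seasonal_amplitude < 0))
    stop("seasonal_amplitude must be non-negative", call. = FALSE)
  if (any(abs(variable_specs$ar) >= 1))
    stop("ar coefficient must lie strictly inside (-1, 1)", call. = FALSE)
  if (!(adjustment_speed > -1 && adjustment_speed < 0))
    stop("adjustment_speed must lie strictly inside (-1, 0)", call. = FALSE)
  if (response_innovation_sd < 0)
    stop("response_innovation_sd must be non-negative", call. = FALSE)
  if (n_months < 24)
    stop("n_months must be at least 24", call. = FALSE)
  cv <- cointegration_vector
  if (length(cv) && is.null(names(cv)))
    stop("cointegration_vector must be named", call. = FALSE)
  unknown <- setdiff(names(cv), variable_specs$name)
  if (length(unknown))
    stop("cointegration_vector names not among regressors: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (response_name %in% variable_specs$name)
    stop("response name '", response_name, "' collides with a regressor",
         call. = FALSE)
  theta <- stats::setNames(rep(0, nrow(variable_specs)), variable_specs$name)
  theta[names(cv)] <- as.numeric(cv)
  structure(list(n_months = as.integer(n_months),
                 variable_specs = variable_specs,
                 theta = theta,
                 adjustment_speed = adjustment_speed,
                 response_innovation_sd = response_innovation_sd,
                 intercept = intercept,
                 response_name = response_name,
                 start_month = start_month,
                 seed = as.integer(seed)),
            class = "dgp_config")
}

#' @export
print.dgp_config <- function(x, ...) {
  cat("Synthetic fire-climate DGP:", x$n_months, "months,",
      nrow(x$variable_specs), "regressors\n")
  cat("  adjustment speed:", x$adjustment_speed,
      " response sd:", x$response_innovation_sd, "\n")
  nz <- x$theta[x$theta != 0]
  cat("  long-run vector:",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = ", ")
      else "(all zero)", "\n")
  invisible(x)
}

#' Study-scale default configuration
#'
#' The package's reference configuration emulating an 18-year monthly
#' fire-climate panel from a temperate steppe grassland: 216 months, eight
#' log-scale climatic regressors (minimum temperature, relative humidity,
#' maximum temperature, precipitation, sunlight hours, wind speed, carbon
#' emission, vapour pressure deficit), a mix of stationary and unit-root
#' regressors, and a single cointegrating relation dominated by wind speed
#' with adjustment speed -0.6.
#'
#' @param seed integer seed.
#' @param n_months number of months (default 216, i.e. 2001--2018).
#' @return a `dgp_config`.
#' @export
xilingol_dgp_config <- function(seed = 1L, n_months = 216L) {
  specs <- data.frame(
    name = c("t_min", "rel_humidity", "t_max", "precip",
             "sunlight", "wind", "cem", "vpd"),
    order = c(1, 1, 0, 1, 1, 0, 1, 1),
    seasonal_amplitude = 0.3,
    innovation_sd = 0.2,
    ar = c(0, 0, 0.7, 0, 0, 0.7, 0, 0)
  )
  dgp_config(
    n_months = n_months,
    variable_specs = specs,
    cointegration_vector = c(wind = 2.0, t_max = 1.0, sunlight = 0.5, cem = 0.3),
    adjustment_speed = -0.6,
    response_innovation_sd = 0.3,
    intercept = 0.2,
    seed = seed
  )
}

#' Generate the synthetic climatic regressors
#'
#' Each order-1 variable is a cumulative sum of independent Gaussian
#' innovations (plus optional drift); each order-0 variable is a stationary
#' AR(1) initialised from its stationary distribution. Every variable then
#' receives an additive sinusoid of period 12 with the configured amplitude
#' (phases are staggered across variables so seasonal terms are not
#' collinear). Uses the RNG stream seeded from `config$seed`.
#'
#' @param config a [dgp_config()].
#' @return a `monthly_panel` of the regressors.
#' @export
generate_regressors <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  set.seed(config$seed)
  n <- config$n_months
  specs <- config$variable_specs
  tt <- seq_len(n)
  out <- matrix(NA_real_, n, nrow(specs),
                dimnames = list(NULL, specs$name))
  for (i in seq_len(nrow(specs))) {
    innov <- stats::rnorm(n, 0, specs$innovation_sd[i])
    if (specs$order[i] == 1) {
      x <- cumsum(innov) + specs$drift[i] * tt
    } else {
      ar <- specs$ar[i]
      x0 <- stats::rnorm(1, 0, specs$innovation_sd[i] / sqrt(1 - ar^2))
      x <- as.numeric(stats::filter(innov, ar, method = "recursive",
                                    init = x0))
    }
    phase <- (i - 1) * pi / 4
    out[, i] <- x + specs$seasonal_amplitude[i] * sin(2 * pi * tt / 12 + phase)
  }
  monthly_panel(out, start_month = config$start_month)
}

#' Generate the response by the error-correction recursion
#'
#' Simulates forward, for \eqn{t \ge 2},
#' \deqn{\Delta y_t = \alpha_0 + s\,(y_{t-1} - \textstyle\sum_j \theta_j x_{j,t-1})
#'   + \varepsilon_t,\qquad \varepsilon_t \sim N(0, \sigma^2)}
#' starting from the implied equilibrium
#' \eqn{y_1 = \sum_j \theta_j x_{j,1} - \alpha_0 / s}. In the level
#' parameterisation of the error-correction ARDL this means the own-level
#' coefficient is \eqn{\delta_0 = s} and each regressor-level coefficient is
#' \eqn{\delta_j = -s\,\theta_j}. Uses the RNG stream seeded from
#' `config$seed + 1` so the recursion is reproducible irrespective of draws
#' made for the regressors.
#'
#' @param regressors `monthly_panel` from [generate_regressors()] with the
#'   same configuration.
#' @param config a [dgp_config()].
#' @return the input panel with the response column appended.
#' @export
generate_response <- function(regressors, config) {
  stopifnot(inherits(regressors, "monthly_panel"), inherits(config, "dgp_config"))
  if (config$response_name %in% panel_vars(regressors))
    stop("response name '", config$response_name,
         "' collides with a regressor", call. = FALSE)
  X <- panel_matrix(regressors, config$variable_specs$name)
  n <- nrow(X)
  set.seed(config$seed + 1L)
  eps <- if (config$response_innovation_sd > 0)
    stats::rnorm(n, 0, config$response_innovation_sd) else numeric(n)
  s <- config$adjustment_speed
  equil <- as.numeric(X %*% config$theta)
  y <- numeric(n)
  y[1L] <- equil[1L] - config$intercept / s
  for (t in 2:n)
    y[t] <- y[t - 1L] + config$intercept + s * (y[t - 1L] - equil[t - 1L]) + eps[t]
  vals <- cbind(as.data.frame(panel_matrix(regressors)),
                stats::setNames(data.frame(y), config$response_name))
  monthly_panel(vals, start_month = regressors$month[1L])
}

#' Generate a complete synthetic fire-climate panel
#'
#' Convenience wrapper: [generate_regressors()] then [generate_response()].
#'
#' @param config a [dgp_config()].
#' @return a `monthly_panel` with regressors and response.
#' @export
simulate_fire_panel <- function(config) {
  generate_response(generate_regressors(config), config)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [dgp_config()].
#' @param path file path.
#' @return `write_dgp_config()` returns `path` invisibly;
#'   `read_dgp_config()` returns a `dgp_config`.
#' @export
write_dgp_config <- function(config, path) {
  stopifnot(inherits(config, "dgp_config"))
  x <- unclass(config)
  x$variable_specs <- as.list(as.data.frame(x$variable_specs))
  x$theta <- as.list(x$theta)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_dgp_config
#' @export
read_dgp_config <- function(path) {
  x <- yaml::read_yaml(path)
  theta <- unlist(x$theta)
  dgp_config(n_months = x$n_months,
             variable_specs = as.data.frame(x$variable_specs),
             cointegration_vector = theta[theta != 0],
             adjustment_speed = x$adjustment_speed,
             response_innovation_sd = x$response_innovation_sd,
             intercept = x$intercept,
             response_name = x$response_name,
             start_month = x$start_month,
             seed = x$seed)
}
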