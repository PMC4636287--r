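#' Simulate the Gbetagamma-coexpression dose-response
#'
#' Predicts the current measured without agonist while increasing amounts of
#' exogenous Gbetagamma are coexpressed, for a channel at fixed surface
#' density. Two scenarios are supported. `"recruited_base"` starts from the
#' Gbetagamma and Galpha pools inferred from that cell's own basal and
#' agonist currents (channel-recruited Gbetagamma); each dose adds exogenous
#' Gbetagamma to the Gbetagamma pool only. `"endogenous_only"` is the
#' classical null scenario: the starting pools are an assumed level of
#' endogenous heterotrimer (equal Galpha and Gbetagamma), again with doses
#' adding Gbetagamma only. Each point is a resting-state solve (Galpha keeps
#' sequestering Gbetagamma; no agonist present). The activation index
#' `R_bg` is the current relative to the zero-dose basal current.
#'
#' @param added_gbg Vector of coexpressed Gbetagamma surface densities
#'   (molecules/um^2), non-negative and increasing.
#' @param channel_density Channel surface density (channels/um^2).
#' @param base_gbg,base_ga Pre-coexpression pools (molecules/um^2); used by
#'   `"recruited_base"`.
#' @param mode `"recruited_base"` or `"endogenous_only"`.
#' @param endogenous_trimer Endogenous heterotrimer level (molecules/um^2),
#'   used by `"endogenous_only"`.
#' @param params,consts,geom Model parameter objects.
#' @return Tibble: `added_gbg`, `gbg_total`, `ga_total`, `i_bg` (uA) and
#'   `r_bg`, with the scenario recorded in a `mode` column.
#' @examples
#' simulate_gbg_dose_response(
#'   added_gbg = c(0, 10, 30), channel_density = 13.75,
#'   base_gbg = 3.16 * 13.75, base_ga = 0.73 * 13.75
#' )
#' @export
simulate_gbg_dose_response <- function(added_gbg,
                                       channel_density,
                                       base_gbg,
                                       base_ga,
                                       mode = c("recruited_base",
                                                "endogenous_only"),
                                       endogenous_trimer = 24,
                                       params = gating_params(),
                                       consts = recording_consts(),
                                       geom = geometry_consts()) {
  mode <- match.arg(mode)
  if (anyNA(added_gbg) || any(added_gbg < 0)) {
    abort("`added_gbg` must be non-negative (molecules/um^2).")
  }
  if (mode == "recruited_base") {
    gbg0 <- base_gbg
    ga0 <- base_ga
  } else {
    gbg0 <- endogenous_trimer
    ga0 <- endogenous_trimer
  }
  isat <- saturating_current(channel_density, params, consts)
  ct <- density_to_concentration(channel_density, geom)
  current_at <- function(add) {
    pool <- gprotein_pool(
      ct,
      density_to_concentration(gbg0 + add, geom),
      density_to_concentration(ga0, geom)
    )
    isat * solve_resting_state(pool, params)$po_fraction
  }
  i0 <- current_at(0)
  if (i0 <= 0) {
    abort("Basal current at zero added Gbetagamma is zero; R_bg is undefined.")
  }
  i <- vapply(added_gbg, current_at, numeric(1))
  tibble::tibble(
    added_gbg = added_gbg,
    gbg_total = gbg0 + added_gbg,
    ga_total = ga0,
    i_bg = i,
    r_bg = i / i0,
    mode = mode
  )
}

#' Fit a hyperbolic decay of the Galpha:channel ratio vs channel density
#'
#' Fits `ga_ratio = y0 + a / density` by ordinary least squares. The model
#' is linear in `1/density`, so the fit is an exact [stats::lm()] (and
#' interpolates exactly through two points).
#'
#' @param data Data frame of per-group estimates.
#' @param density,ga_ratio Columns holding channel density (channels/um^2)
#'   and the Galpha:channel ratio (tidy-eval; defaults `channel_density`,
#'   `ga_per_channel`, the columns produced by [infer_stoichiometry()]).
#' @return An object of class `girk_hyperfit` with elements `y0`, `a` and
#'   the underlying `lm` fit; supports [tidy()], [glance()] and `predict()`.
#' @examples
#' fit <- fit_hyperbolic_ga(
#'   tibble::tibble(channel_density = c(2.74, 9.7, 21.7),
#'                  ga_per_channel = c(1.37, 0.56, 0.33))
#' )
#' predict(fit, c(1, 10, 30))
#' @export
fit_hyperbolic_ga <- function(data,
                              density = channel_density,
                              ga_ratio = ga_per_channel) {
  x <- dplyr::pull(data, {{ density }})
  y <- dplyr::pull(data, {{ ga_ratio }})
  if (length(x) < 2) abort("At least 2 points are needed.")
  if (any(x <= 0)) abort("Densities must be > 0.")
  if (length(unique(x)) < 2) abort("Densities must be distinct.")
  fit <- lm(y ~ I(1 / x))
  structure(
    list(y0 = unname(coef(fit)[1]), a = unname(coef(fit)[2]), fit = fit),
    class = "girk_hyperfit"
  )
}

#' @export
print.girk_hyperfit <- function(x, ...) {
  cat(sprintf("<girk_hyperfit> Ga:GIRK = %.4g + %.4g / density\n", x$y0, x$a))
  invisible(x)
}

#' @rdname fit_hyperbolic_ga
#' @param object,x A `girk_hyperfit` object.
#' @param newdata Channel densities at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.girk_hyperfit <- function(object, newdata, ...) {
  object$y0 + object$a / newdata
}

#' @rdname fit_hyperbolic_ga
#' @method tidy girk_hyperfit
#' @export
tidy.girk_hyperfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("y0", "a"),
    estimate = c(x$y0, x$a),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname fit_hyperbolic_ga
#' @method glance girk_hyperfit
#' @export
glance.girk_hyperfit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = length(s$residuals)
  )
}

#' Simulate the activation index R_a as a function of basal current
#'
#' Reconstructs the inverse R_a-I_basal relation from a density-dependent
#' Galpha availability: for each channel density on the grid, the
#' Gbetagamma pool is a constant multiple of the channel density, the
#' Galpha:channel ratio comes from a hyperbolic decay curve (or any supplied
#' rule), and resting and evoked equilibria give `I_basal`, `I_total` and
#' `R_a = I_total / I_basal`.
#'
#' @param density_grid Channel densities (channels/um^2); default 60 points
#'   spanning 1-30.
#' @param gbg_ratio Constant Gbetagamma:channel ratio (3.5 for oocytes, 3.4
#'   for neurons).
#' @param ga_curve A [fit_hyperbolic_ga()] object, a numeric `c(y0, a)`, a
#'   function of density returning the Galpha:channel ratio, or a single
#'   number for a constant ratio. Negative values are clipped to 0 with a
#'   warning.
#' @param params,consts,geom Model parameter objects.
#' @return Tibble: `channel_density`, `ga_per_channel`, `i_basal`,
#'   `i_total` (uA) and `r_a`.
#' @examples
#' simulate_ra_vs_ibasal(gbg_ratio = 3.5, ga_curve = c(y0 = 0.2, a = 3.2))
#' @export
simulate_ra_vs_ibasal <- function(density_grid = seq(1, 30, length.out = 60),
                                  gbg_ratio = 3.5,
                                  ga_curve,
                                  params = gating_params(),
                                  consts = recording_consts(),
                                  geom = geometry_consts()) {
  if (any(density_grid <= 0)) abort("Densities must be > 0.")
  ga_fun <- if (inherits(ga_curve, "girk_hyperfit")) {
    function(d) predict(ga_curve, d)
  } else if (is.function(ga_curve)) {
    ga_curve
  } else if (is.numeric(ga_curve) && length(ga_curve) == 2) {
    function(d) ga_curve[[1]] + ga_curve[[2]] / d
  } else if (is.numeric(ga_curve) && length(ga_curve) == 1) {
    function(d) rep(ga_curve, length(d))
  } else {
    abort("`ga_curve` must be a girk_hyperfit, c(y0, a), a function, or a constant.")
  }
  ga_ratio <- vapply(density_grid, function(d) ga_fun(d)[[1]], numeric(1))
  if (any(ga_ratio < 0)) {
    warn("Negative Galpha ratios from `ga_curve` clipped to 0.")
    ga_ratio <- pmax(ga_ratio, 0)
  }
  sim <- simulate_currents(
    tibble::tibble(
      channel_density = density_grid,
      gbg_total = gbg_ratio * density_grid,
      ga_total = ga_ratio * density_grid
    ),
    params = params, consts = consts, geom = geom
  )
  tibble::tibble(
    channel_density = density_grid,
    ga_per_channel = ga_ratio,
    i_basal = sim$i_basal,
    i_total = sim$i_total,
    r_a = sim$r_a
  )
}
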