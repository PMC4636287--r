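#' Ground truth for a synthetic per-cell current dataset
#'
#' Describes groups of cells at set channel surface densities with fixed
#' Gbetagamma:channel and Galpha:channel ratios, between-cell density
#' variability and multiplicative measurement noise. The defaults mirror the
#' three oocyte expression groups used throughout: densities 2.74, 9.7 and
#' 21.7 channels/um^2 with Gbetagamma ratios near 3.5 and a Galpha ratio
#' that declines with density, 50 cells per group. Noise is lognormal and
#' multiplicative (currents are positive); the default coefficients of
#' variation (`noise_cv = 0.2` per current, `density_spread_cv = 0.3`
#' between cells) jointly reproduce the per-group dispersion seen in grouped
#' oocyte recordings, where SEM x sqrt(n) / mean is roughly 0.4-0.7.
#'
#' @param groups Data frame with columns `group`, `channel_density`
#'   (channels/um^2), `gbg_per_channel`, `ga_per_channel`, `n_cells`.
#' @param noise_cv CV of the multiplicative lognormal measurement noise,
#'   applied independently to each measured current.
#' @param density_spread_cv CV of the lognormal between-cell spread of
#'   channel density around the group value.
#' @param seed Integer seed; generation is deterministic given the truth.
#' @param cell_profile `"oocyte"` emits whole-cell uA at 24 mM K+, -80 mV;
#'   `"neuron"` emits pA/pF at 25 mM K+, -70 mV (exercising
#'   [normalize_current()] on ingestion).
#' @return An object of class `girk_truth`.
#' @examples
#' synthetic_truth(seed = 7)
#' @export
synthetic_truth <- function(groups = NULL,
                            noise_cv = 0.2,
                            density_spread_cv = 0.3,
                            seed = 1,
                            cell_profile = c("oocyte", "neuron")) {
  cell_profile <- match.arg(cell_profile)
  if (is.null(groups)) {
    groups <- tibble::tibble(
      group = c("low", "intermediate", "high"),
      channel_density = c(2.74, 9.7, 21.7),
      gbg_per_channel = c(3.74, 3.26, 3.48),
      ga_per_channel = c(1.37, 0.56, 0.33),
      n_cells = 50L
    )
  }
  groups <- tibble::as_tibble(groups)
  req <- c("group", "channel_density", "gbg_per_channel",
           "ga_per_channel", "n_cells")
  if (!all(req %in% names(groups))) {
    abort(paste("`groups` must have columns:", paste(req, collapse = ", ")))
  }
  if (any(groups$n_cells < 1)) abort("`n_cells` must be >= 1.")
  if (noise_cv < 0 || density_spread_cv < 0) {
    abort("Coefficients of variation must be >= 0.")
  }
  structure(
    list(
      groups = groups, noise_cv = noise_cv,
      density_spread_cv = density_spread_cv,
      seed = as.integer(seed), cell_profile = cell_profile
    ),
    class = "girk_truth"
  )
}

#' @export
print.girk_truth <- function(x, ...) {
  cat(sprintf(
    "<girk_truth> %d groups, %d cells, noise_cv %.2g, density cv %.2g, seed %d (%s)\n",
    nrow(x$groups), sum(x$groups$n_cells), x$noise_cv,
    x$density_spread_cv, x$seed, x$cell_profile
  ))
  invisible(x)
}

# sdlog of a lognormal with unit mean and coefficient of variation cv
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative lognormal noise factors with mean 1
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lnorm_sdlog(cv)
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic per-cell current table
#'
#' Draws per-cell channel densities around each group density, assembles
#' G-protein pools from the group ratios, forward-solves the resting, evoked
#' and saturating-Gbetagamma states, and applies independent multiplicative
#' noise to `i_basal`, `i_evoked` and `i_bg`. `i_total` is recomputed as
#' `i_basal + i_evoked` after noising and `r_a` per cell from its own
#' currents. Byte-identical output for identical truth (including seed).
#'
#' @param truth A [synthetic_truth()] object.
#' @param params,consts,geom Model parameter objects.
#' @return Tibble with one row per cell: `cell_id`, `group`, `cell_type`,
#'   `units`, `k_out`, `holding`, `channel_density` (true), `i_basal`,
#'   `i_evoked`, `i_total`, `i_bg`, `r_a`. The truth is attached as the
#'   `"truth"` attribute.
#' @examples
#' cells <- generate_cells(synthetic_truth(seed = 7))
#' head(cells)
#' @export
generate_cells <- function(truth,
                           params = gating_params(),
                           consts = recording_consts(),
                           geom = geometry_consts()) {
  stopifnot(inherits(truth, "girk_truth"))
  cells <- withr::with_seed(truth$seed, {
    per_group <- purrr::pmap(truth$groups, function(group, channel_density,
                                                    gbg_per_channel,
                                                    ga_per_channel, n_cells) {
      dens <- channel_density * lnorm_factor(n_cells, truth$density_spread_cv)
      fwd <- simulate_currents(
        tibble::tibble(
          channel_density = dens,
          gbg_total = gbg_per_channel * dens,
          ga_total = ga_per_channel * dens
        ),
        params = params, consts = consts, geom = geom
      )
      ib <- fwd$i_basal * lnorm_factor(n_cells, truth$noise_cv)
      ie <- fwd$i_evoked * lnorm_factor(n_cells, truth$noise_cv)
      ibg <- fwd$i_bg * lnorm_factor(n_cells, truth$noise_cv)
      tibble::tibble(
        group = group, channel_density = dens,
        i_basal = ib, i_evoked = ie, i_total = ib + ie, i_bg = ibg,
        r_a = (ib + ie) / ib
      )
    })
    dplyr::bind_rows(per_group)
  })
  cells <- dplyr::mutate(
    cells,
    cell_id = sprintf("cell%03d", dplyr::row_number()),
    .before = 1
  )
  if (truth$cell_profile == "neuron") {
    to_neuron <- function(v) {
      # oocyte-equivalent uA -> pA/pF at -80 mV -> back to -70 mV
      normalize_current(v, "oocyte", units = "uA", consts = consts) * 33 / 43
    }
    cells <- dplyr::mutate(
      cells,
      dplyr::across(c("i_basal", "i_evoked", "i_total", "i_bg"), to_neuron),
      cell_type = "neuron", units = "pA_pF", k_out = 25, holding = -70
    )
  } else {
    cells <- dplyr::mutate(
      cells,
      cell_type = "oocyte", units = "uA", k_out = 24, holding = -80
    )
  }
  attr(cells, "truth") <- truth
  cells
}

#' Recover stoichiometry from a synthetic dataset and compare to truth
#'
#' Normalizes the per-cell currents to oocyte-equivalent whole-cell uA,
#' averages them per group (inference operates on group means), runs
#' [infer_stoichiometry()], and reports estimates next to the generating
#' truth with relative errors.
#'
#' @param cells Table from [generate_cells()] (truth attached), or any
#'   per-cell table plus an explicit `truth` object.
#' @param truth Optional [synthetic_truth()]; defaults to the attribute.
#' @param params,consts,geom Model parameter objects.
#' @return Tibble: one row per group and parameter (`gbg_per_channel`,
#'   `ga_per_channel`) with `truth`, `estimate` and `rel_error`.
#' @examples
#' cells <- generate_cells(synthetic_truth(seed = 7, noise_cv = 0))
#' recover_from_synthetic(cells)
#' @export
recover_from_synthetic <- function(cells, truth = attr(cells, "truth"),
                                   params = gating_params(),
                                   consts = recording_consts(),
                                   geom = geometry_consts()) {
  if (is.null(truth)) abort("`truth` missing and not attached to `cells`.")
  to_ua <- function(v, cell_type, units, k_out, holding) {
    papf <- purrr::pmap_dbl(
      list(v, cell_type, units, k_out, holding),
      function(v, ct, u, k, h) {
        normalize_current(v, ct, units = u, k_out = k, holding = h,
                          consts = consts)
      }
    )
    papf * consts$capacitance * 1e3 / 1e6  # pA/pF -> oocyte-equivalent uA
  }
  means <- cells %>%
    dplyr::mutate(dplyr::across(
      c("i_basal", "i_evoked", "i_total", "i_bg"),
      ~ to_ua(.x, .data$cell_type, .data$units, .data$k_out, .data$holding)
    )) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(dplyr::across(
      c("i_basal", "i_evoked", "i_total", "i_bg"), mean
    ), .groups = "drop")
  est <- infer_stoichiometry(means, params = params, consts = consts,
                             geom = geom)
  est %>%
    dplyr::select("group", "gbg_per_channel", "ga_per_channel") %>%
    tidyr::pivot_longer(-"group", names_to = "parameter",
                        values_to = "estimate") %>%
    dplyr::left_join(
      truth$groups %>%
        dplyr::select("group", "gbg_per_channel", "ga_per_channel") %>%
        tidyr::pivot_longer(-"group", names_to = "parameter",
                            values_to = "truth"),
      by = c("group", "parameter")
    ) %>%
    dplyr::mutate(
      rel_error = ifelse(.data$truth > 0,
                         (.data$estimate - .data$truth) / .data$truth,
                         .data$estimate - .data$truth)
    ) %>%
    dplyr::select("group", "parameter", "truth", "estimate", "rel_error")
}
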