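# Invert Po/Po,max -> free Gbetagamma (nM). The po fraction is strictly
# increasing in the free concentration (fp non-decreasing), so the root is
# unique; the bracket is expanded until it encloses the target.
invert_po_fraction <- function(target, params) {
  floor_pf <- if (params$variant == "graded_intrinsic") 1 - params$phi else 0
  if (target < floor_pf - 1e-12) {
    abort(sprintf(
      "Target Po/Po,max (%.4g) is below the Gbetagamma-independent floor (%.4g).",
      target, floor_pf
    ))
  }
  if (target >= 1) {
    abort("Target Po/Po,max must be < 1 (saturation bound).")
  }
  if (target <= floor_pf + 1e-15) return(0)
  pf <- function(g) {
    po_fraction(occupancy_fractions(g, params$kd_channel), params)
  }
  upper <- params$kd_channel * 1e6
  while (pf(upper) < target) upper <- upper * 10
  uniroot(function(g) pf(g) - target, c(0, upper), tol = 1e-12)$root
}

#' Infer total available Gbetagamma from the agonist-state current
#'
#' Under saturating agonist the heterotrimer is fully dissociated, so
#' `I_total` reflects the entire Gbetagamma pool available to the channel.
#' The measured current is converted to a target P_o/P_o,max (by dividing by
#' the saturating current at the given channel density), the free Gbetagamma
#' achieving that open probability is found by root-finding, and the total
#' follows from the evoked-state conservation law.
#'
#' @param i_total Total (basal + evoked) whole-cell current under saturating
#'   agonist (uA, oocyte-equivalent).
#' @param channel_density Channel surface density (channels/um^2).
#' @param params A [gating_params()] object.
#' @param consts A [recording_consts()] object.
#' @param geom A [geometry_consts()] object.
#' @return One-row tibble: `gbg_total` (molecules/um^2), `gbg_total_nm`,
#'   `gbg_free_nm`, `gbg_per_channel` and the relative current `residual`.
#' @examples
#' infer_available_gbg(1.92, 2.74)
#' @export
infer_available_gbg <- function(i_total, channel_density,
                                params = gating_params(),
                                consts = recording_consts(),
                                geom = geometry_consts()) {
  if (i_total <= 0) abort("`i_total` must be > 0 (uA).")
  if (channel_density <= 0) abort("`channel_density` must be > 0.")
  isat <- saturating_current(channel_density, params, consts)
  if (i_total >= isat) {
    abort(sprintf(
      "i_total (%.4g uA) is at or above the saturating current %.4g uA at Po,max; the Gbetagamma total is unbounded.",
      i_total, isat
    ))
  }
  g <- invert_po_fraction(i_total / isat, params)
  ct <- density_to_concentration(channel_density, geom)
  gbg_nm <- g + 4 * ct * g / (params$kd_channel + g)
  pool <- gprotein_pool(ct, gbg_nm, 0)
  check <- isat * solve_evoked_state(pool, params)$po_fraction
  dens <- concentration_to_density(gbg_nm, geom)
  tibble::tibble(
    gbg_total = dens,
    gbg_total_nm = gbg_nm,
    gbg_free_nm = g,
    gbg_per_channel = dens / channel_density,
    residual = abs(check - i_total) / i_total
  )
}

#' Infer total available Galpha from the basal current
#'
#' Given the Gbetagamma total (from [infer_available_gbg()]), the basal
#' current determines how much Gbetagamma is sequestered in heterotrimers at
#' rest, and hence the Galpha pool. The measured `i_basal` is mapped to a
#' resting free Gbetagamma concentration by root-finding; the trimer
#' concentration follows from Gbetagamma conservation and the Galpha total
#' from the trimer equilibrium, in closed form.
#'
#' @param i_basal Basal whole-cell current (uA, oocyte-equivalent).
#' @param channel_density Channel surface density (channels/um^2).
#' @param gbg_total Total available Gbetagamma (molecules/um^2).
#' @inheritParams infer_available_gbg
#' @return One-row tibble: `ga_total` (molecules/um^2), `ga_total_nm`,
#'   `ga_per_channel`, `trimer_nm` and the relative current `residual`.
#' @examples
#' infer_available_ga(3.9, 9.7, 31.6)
#' @export
infer_available_ga <- function(i_basal, channel_density, gbg_total,
                               params = gating_params(),
                               consts = recording_consts(),
                               geom = geometry_consts()) {
  if (i_basal <= 0) abort("`i_basal` must be > 0 (uA).")
  if (channel_density <= 0) abort("`channel_density` must be > 0.")
  isat <- saturating_current(channel_density, params, consts)
  ct <- density_to_concentration(channel_density, geom)
  gbg_nm <- density_to_concentration(gbg_total, geom)
  # basal current cannot exceed the prediction with no Galpha at all
  i_ga0 <- isat * solve_evoked_state(gprotein_pool(ct, gbg_nm, 0),
                                     params)$po_fraction
  if (i_basal > i_ga0 * (1 + 1e-9)) {
    abort(sprintf(
      "i_basal (%.4g uA) exceeds the zero-Galpha prediction (%.4g uA) for this Gbetagamma total; no non-negative Galpha can explain it.",
      i_basal, i_ga0
    ))
  }
  g <- invert_po_fraction(i_basal / isat, params)
  trimer <- gbg_nm - g - 4 * ct * g / (params$kd_channel + g)
  trimer <- max(trimer, 0)
  ga_nm <- if (g > 0) trimer * (params$kd_trimer + g) / g else Inf
  pool <- gprotein_pool(ct, gbg_nm, ga_nm)
  check <- isat * solve_resting_state(pool, params)$po_fraction
  dens <- concentration_to_density(ga_nm, geom)
  tibble::tibble(
    ga_total = dens,
    ga_total_nm = ga_nm,
    ga_per_channel = dens / channel_density,
    trimer_nm = trimer,
    residual = abs(check - i_basal) / i_basal
  )
}

#' Infer functional stoichiometry from grouped current measurements
#'
#' The two-step headline computation, applied per row of a measurement
#' table: (1) channel density from the saturating-Gbetagamma current `i_bg`
#' (or from `i_total` scaled by an assumed `i_bg`/`i_total` ratio when `i_bg`
#' was not measured); (2) total available Gbetagamma from `i_total`; (3)
#' total available Galpha from `i_basal`. Rows for which a current exceeds
#' its feasibility bound are flagged (`feasible = FALSE`, diagnostics in
#' `note`) rather than dropped.
#'
#' @param data Data frame with columns `i_basal`, `i_total` (uA,
#'   oocyte-equivalent) and, for `density_source = "from_ibg"`, `i_bg`;
#'   optional `group` labels are carried through. `i_total` is backfilled
#'   from `i_basal + i_evoked` when absent.
#' @param params,consts,geom Model parameter objects.
#' @param density_source `"from_ibg"` (default) counts channels from the
#'   measured `i_bg`; `"from_itotal_ratio"` assumes
#'   `i_bg = ibg_over_itotal * i_total`.
#' @param ibg_over_itotal Assumed `i_bg`/`i_total` ratio (default 2, the
#'   midpoint of the observed 1.6-2.2 range).
#' @return A tibble of class `girk_stoich`, one row per input row, with
#'   channel density, Gbetagamma and Galpha totals (molecules/um^2 and nM),
#'   per-channel ratios, solver residuals and feasibility flags. The model
#'   parameters are attached as attributes and reported by [glance()].
#' @examples
#' table1 <- read_measurements(girk_example("table1_oocytes.csv"))
#' infer_stoichiometry(table1)
#' @export
infer_stoichiometry <- function(data,
                                params = gating_params(),
                                consts = recording_consts(),
                                geom = geometry_consts(),
                                density_source = c("from_ibg",
                                                   "from_itotal_ratio"),
                                ibg_over_itotal = 2) {
  density_source <- match.arg(density_source)
  data <- tibble::as_tibble(data)
  if (!"i_total" %in% names(data) &&
      all(c("i_basal", "i_evoked") %in% names(data))) {
    data$i_total <- data$i_basal + data$i_evoked
  }
  req <- c("i_basal", "i_total")
  if (density_source == "from_ibg") req <- c(req, "i_bg")
  if (!all(req %in% names(data))) {
    abort(paste("`data` must have columns:", paste(req, collapse = ", ")))
  }
  if (!"group" %in% names(data)) data$group <- as.character(seq_len(nrow(data)))

  rows <- purrr::pmap(
    list(data$group, data$i_basal, data$i_total,
         if (density_source == "from_ibg") data$i_bg else data$i_total),
    function(group, i_basal, i_total, i_ref) {
      out <- tibble::tibble(
        group = group, channel_density = NA_real_,
        gbg_total = NA_real_, gbg_total_nm = NA_real_,
        gbg_per_channel = NA_real_,
        ga_total = NA_real_, ga_total_nm = NA_real_,
        ga_per_channel = NA_real_,
        residual_gbg = NA_real_, residual_ga = NA_real_,
        feasible = FALSE, note = NA_character_
      )
      tryCatch({
        if (i_basal > i_total * (1 + 1e-6)) {
          abort("i_basal exceeds i_total.")
        }
        i_bg <- if (density_source == "from_ibg") i_ref else
          ibg_over_itotal * i_ref
        dens <- channels_from_ibg(i_bg, params$po_max,
                                  consts)$channel_density
        gbg <- infer_available_gbg(i_total, dens, params, consts, geom)
        ga <- infer_available_ga(i_basal, dens, gbg$gbg_total,
                                 params, consts, geom)
        out$channel_density <- dens
        out$gbg_total <- gbg$gbg_total
        out$gbg_total_nm <- gbg$gbg_total_nm
        out$gbg_per_channel <- gbg$gbg_per_channel
        out$ga_total <- ga$ga_total
        out$ga_total_nm <- ga$ga_total_nm
        out$ga_per_channel <- ga$ga_per_channel
        out$residual_gbg <- gbg$residual
        out$residual_ga <- ga$residual
        out$feasible <- TRUE
        out
      }, error = function(e) {
        out$note <- conditionMessage(e)
        out
      })
    }
  )
  res <- dplyr::bind_rows(rows)
  attr(res, "params") <- params
  attr(res, "consts") <- consts
  attr(res, "geom") <- geom
  attr(res, "density_source") <- density_source
  class(res) <- c("girk_stoich", class(res))
  res
}

#' @rdname infer_stoichiometry
#' @param x A `girk_stoich` tibble.
#' @param ... Unused.
#' @method tidy girk_stoich
#' @export
tidy.girk_stoich <- function(x, ...) {
  x %>%
    dplyr::select("group", "channel_density", "gbg_total", "ga_total",
                  "gbg_per_channel", "ga_per_channel", "feasible") %>%
    tidyr::pivot_longer(
      cols = c("gbg_total", "ga_total", "gbg_per_channel", "ga_per_channel"),
      names_to = "term", values_to = "estimate"
    )
}

#' @rdname infer_stoichiometry
#' @method glance girk_stoich
#' @export
glance.girk_stoich <- function(x, ...) {
  p <- attr(x, "params")
  g <- attr(x, "geom")
  tibble::tibble(
    variant = p$variant,
    kd_channel = p$kd_channel,
    kd_trimer = p$kd_trimer,
    po_max = p$po_max,
    width_nm = g$width,
    density_source = attr(x, "density_source"),
    n_groups = nrow(x),
    n_feasible = sum(x$feasible),
    max_residual = {
      r <- c(x$residual_gbg, x$residual_ga)
      if (any(!is.na(r))) max(r, na.rm = TRUE) else NA_real_
    }
  )
}

#' Sensitivity sweep of the stoichiometry inference
#'
#' Re-runs [infer_stoichiometry()] over a grid of values of one model
#' parameter, holding everything else fixed. Supported parameters:
#' `kd_channel` (nM), `width` (nm), `phi_intrinsic` (intrinsic open
#' probability as a fraction of `po_max`; switches the gating variant to
#' `"graded_intrinsic"` with `phi = 1 - value`), `ibg_over_itotal`
#' (channel-density assumption; switches `density_source`), and `po_max`.
#' Per-point failures are recorded via the `feasible`/`note` columns; the
#' sweep always completes.
#'
#' @param data Measurement table as for [infer_stoichiometry()].
#' @param parameter One of `"kd_channel"`, `"width"`, `"phi_intrinsic"`,
#'   `"ibg_over_itotal"`, `"po_max"`.
#' @param grid Strictly increasing numeric vector of parameter values.
#' @param params,consts,geom Baseline parameter objects.
#' @param ... Passed on to [infer_stoichiometry()].
#' @return Long tibble: one row per grid point and group, with columns
#'   `parameter`, `value` and the estimate columns of [infer_stoichiometry()].
#' @examples
#' table1 <- read_measurements(girk_example("table1_oocytes.csv"))
#' sensitivity_sweep(table1, "kd_channel", c(5, 50, 100))
#' @export
sensitivity_sweep <- function(data, parameter, grid,
                              params = gating_params(),
                              consts = recording_consts(),
                              geom = geometry_consts(),
                              ...) {
  choices <- c("kd_channel", "width", "phi_intrinsic",
               "ibg_over_itotal", "po_max")
  parameter <- match.arg(parameter, choices)
  if (length(grid) == 0) abort("`grid` must be non-empty.")
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  purrr::map_dfr(grid, function(v) {
    p <- params
    g <- geom
    extra <- list(...)
    if (parameter == "kd_channel") {
      p <- modify_gating(p, kd_channel = v)
    } else if (parameter == "po_max") {
      p <- modify_gating(p, po_max = v)
    } else if (parameter == "phi_intrinsic") {
      p <- modify_gating(p, variant = "graded_intrinsic", phi = 1 - v)
    } else if (parameter == "width") {
      g <- geometry_consts(width = v, avogadro = geom$avogadro)
    }
    args <- c(list(data = data, params = p, consts = consts, geom = g), extra)
    if (parameter == "ibg_over_itotal") {
      args$density_source <- "from_itotal_ratio"
      args$ibg_over_itotal <- v
    }
    est <- do.call(infer_stoichiometry, args)
    dplyr::bind_cols(
      tibble::tibble(parameter = parameter, value = v),
      tibble::as_tibble(est)
    )
  })
}

# Rebuild a gating_params object with some fields replaced, revalidating.
modify_gating <- function(params, ...) {
  upd <- utils::modifyList(
    params[c("variant", "fp", "po_max", "phi", "kd_channel", "kd_trimer",
             "kon_trimer", "koff_trimer")],
    list(...)
  )
  do.call(gating_params, upd)
}
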