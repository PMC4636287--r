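#' Binomial occupancy fractions of the four Gbetagamma-binding sites
#'
#' Steady-state fractions of channels with 0..4 bound Gbetagamma at a given
#' free Gbetagamma concentration. Binding is sequential with identical,
#' occupancy-independent site affinity; the statistical factors of the four
#' binding steps (1/4, 2/3, 3/2, 4 times `kd_channel`) make the stationary
#' distribution binomial with per-site occupancy `u/(1+u)`, `u =
#' gbg_free/kd_channel`. The closed form is used for numerical stability at
#' extreme occupancies; it is identical to solving the four mass-action
#' equilibria with the channel conservation law directly.
#'
#' @param gbg_free Free Gbetagamma concentration (nM), scalar or vector.
#' @param kd_channel Per-site dissociation constant (nM).
#' @return For scalar input, a named numeric vector `phi0..phi4` summing to
#'   1; for vector input, a matrix with one row per input value.
#' @examples
#' occupancy_fractions(0, 50)
#' occupancy_fractions(50, 50) # (1,4,6,4,1)/16
#' @export
occupancy_fractions <- function(gbg_free, kd_channel = 50) {
  if (anyNA(gbg_free) || any(gbg_free < 0)) {
    abort("`gbg_free` must be non-negative (nM).")
  }
  if (!is.numeric(kd_channel) || kd_channel <= 0) {
    abort("`kd_channel` must be > 0 (nM).")
  }
  p <- gbg_free / (gbg_free + kd_channel)
  out <- vapply(p, function(pi) {
    x <- 0:4
    choose(4, x) * pi^x * (1 - pi)^(4 - x)
  }, numeric(5))
  rownames(out) <- paste0("phi", 0:4)
  if (length(gbg_free) == 1L) out[, 1L] else t(out)
}

#' Open probability as a fraction of the maximum
#'
#' Combines an occupancy distribution with the gating variant: the graded
#' model sums the fractional open probabilities of the occupied states, the
#' concerted model opens only the fully occupied channel, and the
#' intrinsic-activity extension adds a Gbetagamma-independent floor
#' `1 - phi`.
#'
#' @param occupancy Numeric length-5 vector of occupancy fractions
#'   (phi0..phi4), summing to 1.
#' @param params A [gating_params()] object.
#' @return P_o / P_o,max (dimensionless scalar in \[0, 1\]).
#' @examples
#' po_fraction(occupancy_fractions(50, 50), gating_params())
#' @export
po_fraction <- function(occupancy, params = gating_params()) {
  stopifnot(inherits(params, "girk_gating"))
  if (length(occupancy) != 5L || anyNA(occupancy)) {
    abort("`occupancy` must be a numeric length-5 vector (phi0..phi4).")
  }
  if (abs(sum(occupancy) - 1) > 1e-6 || any(occupancy < -1e-12)) {
    abort("`occupancy` must be a normalized probability vector.")
  }
  graded <- sum(params$fp * occupancy[2:5])
  switch(params$variant,
    graded = graded,
    concerted = occupancy[[5]],
    graded_intrinsic = params$phi * graded + (1 - params$phi)
  )
}

# Conservation residual for free Gbetagamma. `ga_total = 0` and
# `trimer = FALSE` give the agonist (evoked) case where the heterotrimer is
# fully dissociated; otherwise the trimer is eliminated analytically via
# trimer = ga_total * g / (kd_trimer + g). Strictly increasing in `g`.
gbg_residual <- function(g, pool, params, trimer = TRUE) {
  kd <- params$kd_channel
  bound <- 4 * pool$c_total * g / (kd + g)
  tri <- if (trimer) pool$ga_total * g / (params$kd_trimer + g) else 0
  g + tri + bound - pool$gbg_total
}

# Root of the conservation residual on [0, gbg_total].
solve_gbg_free <- function(pool, params, trimer = TRUE) {
  if (pool$gbg_total <= 0) return(0)
  f <- function(g) gbg_residual(g, pool, params, trimer)
  if (f(pool$gbg_total) <= 0) return(pool$gbg_total)
  uniroot(f, c(0, pool$gbg_total), tol = 1e-12)$root
}

girk_state <- function(gbg_free, pool, params, mode) {
  occ <- occupancy_fractions(gbg_free, params$kd_channel)
  cvec <- setNames(pool$c_total * occ, paste0("C", 0:4))
  if (mode == "evoked") {
    trimer <- 0
    ga_free <- pool$ga_total
  } else {
    trimer <- pool$ga_total * gbg_free / (params$kd_trimer + gbg_free)
    ga_free <- pool$ga_total - trimer
  }
  bound <- sum((0:4) * cvec)
  gbg_res <- (gbg_free + trimer + bound - pool$gbg_total) /
    max(pool$gbg_total, 1)
  pf <- po_fraction(occ, params)
  structure(
    list(
      gbg_free = gbg_free, ga_free = ga_free, trimer = trimer,
      c = cvec, occupancy = occ,
      po_fraction = pf, po = params$po_max * pf,
      mode = mode, pool = pool, params = params,
      residual = gbg_res
    ),
    class = "girk_state"
  )
}

#' Steady state under saturating agonist (complete trimer dissociation)
#'
#' Under saturating agonist all Galpha is GTP-bound and dissociated from
#' Gbetagamma, so the whole Gbetagamma pool partitions between free dimer and
#' channel-bound states only. The free concentration is the unique root of
#' the Gbetagamma conservation law, found by bracketed root-finding on
#' \[0, gbg_total\] (the residual is strictly increasing).
#'
#' @param pool A [gprotein_pool()] object.
#' @param params A [gating_params()] object.
#' @return A `girk_state` object: free/bound species (nM), occupancy
#'   fractions, `po_fraction` (P_o/P_o,max) and `po`.
#' @examples
#' solve_evoked_state(gprotein_pool(455, 1700, 620))
#' @export
solve_evoked_state <- function(pool, params = gating_params()) {
  stopifnot(inherits(pool, "girk_pool"), inherits(params, "girk_gating"))
  g <- solve_gbg_free(pool, params, trimer = FALSE)
  girk_state(g, pool, params, mode = "evoked")
}

#' Resting steady state (spontaneous heterotrimer dissociation)
#'
#' Without agonist, free Gbetagamma is set jointly by the channel-binding
#' equilibria and the high-affinity Galpha(GDP)-Gbetagamma heterotrimer
#' equilibrium. The trimer concentration is eliminated analytically
#' (`trimer = ga_total * g / (kd_trimer + g)`), leaving a single strictly
#' monotone conservation equation in the free Gbetagamma concentration.
#'
#' @inheritParams solve_evoked_state
#' @return A `girk_state` object (see [solve_evoked_state()]); `ga_free` and
#'   `trimer` are filled from the trimer equilibrium.
#' @examples
#' solve_resting_state(gprotein_pool(455, 1700, 620))
#' @export
solve_resting_state <- function(pool, params = gating_params()) {
  stopifnot(inherits(pool, "girk_pool"), inherits(params, "girk_gating"))
  g <- solve_gbg_free(pool, params, trimer = TRUE)
  girk_state(g, pool, params, mode = "resting")
}

#' @export
print.girk_state <- function(x, ...) {
  cat(sprintf(
    "<girk_state> %s: free Gbg %.4g nM, trimer %.4g nM, Po/Po,max %.4g\n",
    x$mode, x$gbg_free, x$trimer, x$po_fraction
  ))
  invisible(x)
}

#' @rdname solve_evoked_state
#' @param x A `girk_state` object.
#' @param ... Unused.
#' @method tidy girk_state
#' @export
tidy.girk_state <- function(x, ...) {
  tibble::tibble(
    species = c("gbg_free", "ga_free", "trimer", names(x$c)),
    concentration_nm = c(x$gbg_free, x$ga_free, x$trimer, unname(x$c))
  )
}

#' Forward-simulate whole-cell currents for channel/G-protein pools
#'
#' For each row (one group or cell) the resting and evoked equilibria are
#' solved and converted to whole-cell currents via
#' `I = i_single * Po * N / f_sc`. Densities are in molecules/um^2 and
#' converted internally to submembrane concentrations.
#'
#' @param data Data frame with columns `channel_density`, `gbg_total` and
#'   `ga_total` (all molecules/um^2).
#' @param params A [gating_params()] object.
#' @param consts A [recording_consts()] object.
#' @param geom A [geometry_consts()] object.
#' @return The input with columns `i_basal`, `i_evoked`, `i_total`, `i_bg`
#'   (uA, oocyte whole-cell equivalents) and `r_a` appended.
#' @examples
#' simulate_currents(
#'   tibble::tibble(channel_density = 9.7, gbg_total = 31.6, ga_total = 5.4)
#' )
#' @export
simulate_currents <- function(data,
                              params = gating_params(),
                              consts = recording_consts(),
                              geom = geometry_consts()) {
  req <- c("channel_density", "gbg_total", "ga_total")
  if (!all(req %in% names(data))) {
    abort(paste("`data` must have columns:", paste(req, collapse = ", ")))
  }
  res <- purrr::pmap(
    dplyr::select(data, dplyr::all_of(req)),
    function(channel_density, gbg_total, ga_total) {
      pool <- gprotein_pool(
        density_to_concentration(channel_density, geom),
        density_to_concentration(gbg_total, geom),
        density_to_concentration(ga_total, geom)
      )
      isat <- saturating_current(channel_density, params, consts)
      rest <- solve_resting_state(pool, params)
      evok <- solve_evoked_state(pool, params)
      ib <- isat * rest$po_fraction
      it <- isat * evok$po_fraction
      tibble::tibble(
        i_basal = ib, i_evoked = it - ib, i_total = it, i_bg = isat,
        r_a = ifelse(ib > 0, it / ib, NA_real_)
      )
    }
  )
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(res))
}

# Whole-cell current (uA) at Po = Po,max for a given channel surface density.
saturating_current <- function(channel_density,
                               params = gating_params(),
                               consts = recording_consts()) {
  n <- channel_density * consts$membrane_area
  consts$i_single * params$po_max * n / consts$f_sc * 1e-6
}
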