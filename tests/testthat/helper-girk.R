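# Shared fixtures and independent oracles.

# Group means of the three oocyte expression groups (whole-cell uA) and the
# surface densities derived from the saturating-Gbetagamma currents.
oocyte_groups <- tibble::tibble(
  group = c("low", "intermediate", "high"),
  i_basal = c(0.73, 3.9, 13.36),
  i_evoked = c(1.19, 2.3, 3.84),
  i_total = c(1.92, 6.2, 17.2),
  i_bg = c(3.49, 12.34, 27.6)
)

# Independent oracle for the occupancy distribution: solve the four
# sequential mass-action equilibria (with statistical factors 1/4, 2/3,
# 3/2, 4) plus channel conservation as an explicit linear system in C0..C4.
occupancy_linear_oracle <- function(gbg_free, kd, c_total = 1) {
  g <- gbg_free
  a <- matrix(0, 5, 5)
  a[1, 1:2] <- c(g, -kd / 4)        # C0*g = 1/4 KD C1
  a[2, 2:3] <- c(g, -2 * kd / 3)    # C1*g = 2/3 KD C2
  a[3, 3:4] <- c(g, -3 * kd / 2)    # C2*g = 3/2 KD C3
  a[4, 4:5] <- c(g, -4 * kd)        # C3*g = 4 KD C4
  a[5, ] <- 1                       # sum C = c_total
  b <- c(0, 0, 0, 0, c_total)
  solve(a, b) / c_total
}

# Brute-force oracle for the resting equilibrium: 2-D grid search over
# (free Gbetagamma, free Galpha). The trimer concentration at each grid
# point follows from Galpha conservation (t = ga_total - a); the squared,
# scaled residuals of the trimer mass-action equilibrium and of Gbetagamma
# conservation are minimized by iterative grid refinement.
# Free concentrations are strictly positive but can be orders of magnitude
# below the totals, so the search works on log10-spaced grids.
resting_grid_oracle <- function(pool, params, n = 81, passes = 8) {
  occ_bound <- function(g) {
    p <- g / (g + params$kd_channel)
    4 * pool$c_total * p
  }
  lo_g <- log10(pool$gbg_total) - 10; hi_g <- log10(pool$gbg_total)
  has_ga <- pool$ga_total > 0
  lo_a <- if (has_ga) log10(pool$ga_total) - 10 else 0
  hi_a <- if (has_ga) log10(pool$ga_total) else 0
  best <- c(NA, NA)
  sb <- max(pool$gbg_total, 1)
  sa <- max(pool$ga_total, 1)
  for (k in seq_len(passes)) {
    gs <- 10^seq(lo_g, hi_g, length.out = n)
    as <- if (has_ga) 10^seq(lo_a, hi_a, length.out = n) else 0
    tri <- pool$ga_total - as                       # from Galpha conservation
    # trimer equilibrium: g * a = kd_trimer * t
    r_eq <- (outer(gs, as) - params$kd_trimer * rep(tri, each = n)) /
      (params$kd_trimer * sa)
    r_gbg <- (gs + occ_bound(gs) - pool$gbg_total + rep(tri, each = n)) / sb
    obj <- r_eq^2 + r_gbg^2
    idx <- arrayInd(which.min(obj), dim(obj))
    lg <- seq(lo_g, hi_g, length.out = n)
    la <- if (has_ga) seq(lo_a, hi_a, length.out = n) else 0
    best <- c(gs[idx[1]], if (has_ga) as[idx[2]] else 0)
    dg <- if (n > 1) diff(lg[1:2]) else 0
    da <- if (has_ga) diff(la[1:2]) else 0
    lo_g <- lg[idx[1]] - 2 * dg
    hi_g <- min(log10(pool$gbg_total), lg[idx[1]] + 2 * dg)
    if (has_ga) {
      lo_a <- la[idx[2]] - 2 * da
      hi_a <- min(log10(pool$ga_total), la[idx[2]] + 2 * da)
    }
  }
  list(gbg_free = best[1], ga_free = best[2])
}

# Random pools spanning the physiological density and ratio ranges.
random_pools <- function(n, seed, geom = geometry_consts()) {
  withr::with_seed(seed, {
    tibble::tibble(
      channel_density = stats::runif(n, 1, 30),
      gbg_ratio = stats::runif(n, 1, 6),
      ga_ratio = stats::runif(n, 0, 4)
    )
  })
}

pool_from_row <- function(row, geom = geometry_consts()) {
  gprotein_pool(
    density_to_concentration(row$channel_density, geom),
    density_to_concentration(row$channel_density * row$gbg_ratio, geom),
    density_to_concentration(row$channel_density * row$ga_ratio, geom)
  )
}

# Residuals of the full equation system at a solved state.
state_residuals <- function(state) {
  pool <- state$pool
  params <- state$params
  g <- state$gbg_free
  cvec <- state$c
  # four binding equilibria (relative)
  kd <- params$kd_channel
  eq <- c(
    cvec[1] * g - kd / 4 * cvec[2],
    cvec[2] * g - 2 * kd / 3 * cvec[3],
    cvec[3] * g - 3 * kd / 2 * cvec[4],
    cvec[4] * g - 4 * kd * cvec[5]
  ) / max(pool$c_total * kd, 1e-12)
  chan <- (sum(cvec) - pool$c_total) / max(pool$c_total, 1e-12)
  gbg <- (g + state$trimer + sum((0:4) * cvec) - pool$gbg_total) /
    max(pool$gbg_total, 1e-12)
  ga <- if (state$mode == "resting") {
    (state$ga_free + state$trimer - pool$ga_total) / max(pool$ga_total, 1e-12)
  } else {
    0
  }
  c(binding = max(abs(eq)), channel = abs(chan), gbg = abs(gbg), ga = abs(ga))
}
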