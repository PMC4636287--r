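test_that("occupancy fractions match the direct linear-system solution", {
  # closed-form binomial vs explicit solve of the four equilibria + conservation
  cases <- expand.grid(
    g = c(0.01, 1, 12.5, 50, 200, 5000),
    kd = c(5, 50, 100)
  )
  for (i in seq_len(nrow(cases))) {
    got <- occupancy_fractions(cases$g[i], cases$kd[i])
    want <- occupancy_linear_oracle(cases$g[i], cases$kd[i])
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("occupancy limits and normalization behave", {
  expect_equal(unname(occupancy_fractions(0, 50)), c(1, 0, 0, 0, 0))
  expect_equal(unname(occupancy_fractions(50, 50)),
               c(1, 4, 6, 4, 1) / 16, tolerance = 1e-12)
  sat <- occupancy_fractions(1e6 * 50, 50)
  expect_gt(sat[["phi4"]], 0.9999)
  for (g in c(0.3, 7, 90, 3e4)) {
    expect_equal(sum(occupancy_fractions(g, 50)), 1, tolerance = 1e-12)
  }
  expect_error(occupancy_fractions(-1, 50), "non-negative")
  expect_error(occupancy_fractions(10, 0), "kd_channel")
})

test_that("po_fraction implements the three gating variants", {
  expect_equal(po_fraction(c(0, 0, 0, 0, 1), gating_params()), 1)
  # two bound Gbetagamma open at 6% of maximum
  expect_equal(po_fraction(c(0, 0, 1, 0, 0), gating_params()), 0.06)
  gi <- gating_params(variant = "graded_intrinsic", phi = 0.9)
  expect_equal(po_fraction(c(1, 0, 0, 0, 0), gi), 0.1, tolerance = 1e-12)
  # concerted counts only the fully occupied state
  occ <- occupancy_fractions(75, 50)
  expect_equal(po_fraction(occ, gating_params(variant = "concerted")),
               occ[["phi4"]])
  expect_error(po_fraction(c(0.5, 0.1, 0, 0, 0), gating_params()),
               "normalized")
})

test_that("graded po dominates concerted and degenerate fp reduces to it", {
  graded <- gating_params()
  conc <- gating_params(variant = "concerted")
  degen <- gating_params(fp = c(0, 0, 0, 1))
  for (g in c(0.5, 5, 50, 500, 5e4)) {
    occ <- occupancy_fractions(g, 50)
    expect_gte(po_fraction(occ, graded), po_fraction(occ, conc))
    expect_equal(po_fraction(occ, degen), po_fraction(occ, conc))
  }
})

test_that("solved states satisfy every equilibrium and conservation law", {
  pools <- random_pools(60, seed = 101)
  params <- gating_params()
  for (i in seq_len(nrow(pools))) {
    pool <- pool_from_row(pools[i, ])
    for (solver in list(solve_resting_state, solve_evoked_state)) {
      st <- solver(pool, params)
      res <- state_residuals(st)
      expect_lt(res[["binding"]], 1e-6)
      expect_lt(res[["channel"]], 1e-9)
      expect_lt(res[["gbg"]], 1e-6)
      expect_lt(res[["ga"]], 1e-6)
      expect_equal(sum(st$occupancy), 1, tolerance = 1e-10)
      expect_true(all(st$c >= 0) && st$trimer >= 0 && st$ga_free >= -1e-12)
    }
  }
})

test_that("resting equilibrium matches a brute-force 2-D grid search", {
  pools <- random_pools(100, seed = 202)
  params <- gating_params()
  for (i in seq_len(nrow(pools))) {
    pool <- pool_from_row(pools[i, ])
    st <- solve_resting_state(pool, params)
    oracle <- resting_grid_oracle(pool, params)
    # agreement well within the refined grid resolution
    expect_lt(abs(st$gbg_free - oracle$gbg_free),
              1e-8 * max(pool$gbg_total, 1))
    expect_lt(abs(st$ga_free - oracle$ga_free),
              1e-8 * max(pool$ga_total, 1))
  }
})

test_that("limiting cases of the resting solve are exact", {
  params <- gating_params()
  # no Galpha: resting state coincides with the evoked state
  pool <- gprotein_pool(500, 2000, 0)
  expect_equal(solve_resting_state(pool, params)$gbg_free,
               solve_evoked_state(pool, params)$gbg_free, tolerance = 1e-10)
  # no Gbetagamma at all
  st0 <- solve_resting_state(gprotein_pool(500, 0, 100), params)
  expect_equal(st0$gbg_free, 0)
  expect_equal(st0$po, 0)
  # overwhelming Galpha sequesters everything
  stinf <- solve_resting_state(gprotein_pool(500, 2000, 1e12), params)
  expect_lt(stinf$gbg_free, 1e-6)
  expect_lt(stinf$po_fraction, 1e-6)
})

test_that("open probability is monotone in the G-protein pools", {
  params <- gating_params()
  po_at <- function(gbg, ga) {
    solve_resting_state(gprotein_pool(800, gbg, ga), params)$po
  }
  gbg_ladder <- vapply(seq(100, 8000, length.out = 15), po_at,
                       numeric(1), ga = 500)
  expect_true(all(diff(gbg_ladder) > 0))
  ga_ladder <- vapply(seq(0, 5000, length.out = 15),
                      function(a) po_at(3000, a), numeric(1))
  expect_true(all(diff(ga_ladder) < 0))
})

test_that("po saturates at po_max as Gbetagamma becomes overwhelming", {
  params <- gating_params()
  # deficit from po_max is dominated by the triply occupied state:
  # 1 - sum(fp * phi) ~ 4 * (1 - fp[3]) / u, i.e. ~3e-3 at u = 1e3
  gap_at <- function(u) {
    pool <- gprotein_pool(10, u * params$kd_channel + 40, 0)
    st <- solve_evoked_state(pool, params)
    (params$po_max - st$po) / params$po_max
  }
  expect_lt(gap_at(1e3), 3.1e-3)
  expect_lt(gap_at(1e4), 1e-3)
  gaps <- vapply(10^(1:6), gap_at, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("gating parameter validation enforces the model's invariants", {
  expect_error(gating_params(fp = c(0.2, 0.1, 0.3, 1)), "non-decreasing")
  expect_error(gating_params(fp = c(0.01, 0.06, 0.26, 0.9)), "non-decreasing")
  expect_error(gating_params(po_max = 0), "po_max")
  expect_error(gating_params(kd_channel = -5), "kd_channel")
  # koff/kon must agree with kd_trimer to within 5%
  expect_error(gating_params(kd_trimer = 3), "inconsistent")
  expect_silent(gating_params(kd_trimer = 1.857))
  expect_error(gprotein_pool(-1, 10), "non-negative")
})

test_that("simulate_currents reproduces the forward map row-wise", {
  sim <- simulate_currents(tibble::tibble(
    channel_density = c(2.74, 9.7),
    gbg_total = c(10.2, 31.6),
    ga_total = c(3.75, 5.4)
  ))
  expect_equal(sim$i_total, sim$i_basal + sim$i_evoked)
  expect_equal(sim$r_a, sim$i_total / sim$i_basal)
  # saturating current equals the channel-counting identity
  expect_equal(
    channels_from_ibg(sim$i_bg)$channel_density,
    sim$channel_density,
    tolerance = 1e-10
  )
})
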