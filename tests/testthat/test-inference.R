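test_that("inference reproduces the per-group stoichiometry table", {
  est <- infer_stoichiometry(oocyte_groups)
  expect_true(all(est$feasible))
  expect_equal(est$channel_density, c(2.74, 9.7, 21.7), tolerance = 0.01)
  expect_equal(est$gbg_total, c(10.2, 31.6, 75.5), tolerance = 0.03)
  expect_equal(est$gbg_per_channel, c(3.74, 3.26, 3.48), tolerance = 0.03)
  expect_equal(est$ga_total, c(3.75, 5.4, 7.2), tolerance = 0.03)
  expect_equal(est$ga_per_channel, c(1.37, 0.56, 0.33), tolerance = 0.03)
  expect_true(all(c(est$residual_gbg, est$residual_ga) < 1e-9))
})

test_that("concerted-variant estimates stay within 20% of graded ones", {
  graded <- infer_stoichiometry(oocyte_groups)
  conc <- infer_stoichiometry(oocyte_groups,
                              params = gating_params(variant = "concerted"))
  expect_equal(conc$gbg_total[1], 11.3, tolerance = 0.03)
  rel <- abs(conc$gbg_total - graded$gbg_total) / graded$gbg_total
  expect_true(all(rel < 0.2))
  rel_ga <- abs(conc$ga_total - graded$ga_total) / graded$ga_total
  expect_true(all(rel_ga < 0.35))
})

test_that("forward-inverse roundtrip is exact at zero noise", {
  pools <- random_pools(200, seed = 303)
  sim <- simulate_currents(dplyr::transmute(
    pools,
    channel_density,
    gbg_total = channel_density * gbg_ratio,
    ga_total = channel_density * ga_ratio
  ))
  for (i in seq_len(nrow(sim))) {
    gbg <- infer_available_gbg(sim$i_total[i], sim$channel_density[i])
    expect_lt(abs(gbg$gbg_total - sim$gbg_total[i]) / sim$gbg_total[i], 1e-5)
    if (sim$ga_total[i] > 1e-6) {
      ga <- infer_available_ga(sim$i_basal[i], sim$channel_density[i],
                               gbg$gbg_total)
      expect_lt(abs(ga$ga_total - sim$ga_total[i]) /
                  max(sim$ga_total[i], 1), 1e-5)
    }
  }
})

test_that("inferred totals are monotone in the measured currents", {
  i_tot <- seq(0.5, 3.3, length.out = 12)
  gbg <- vapply(i_tot, function(i) {
    infer_available_gbg(i, 2.74)$gbg_total
  }, numeric(1))
  expect_true(all(diff(gbg) > 0))
  ga <- vapply(seq(0.2, 1.8, length.out = 12), function(i) {
    infer_available_ga(i, 2.74, 10.2)$ga_total
  }, numeric(1))
  expect_true(all(diff(ga) < 0))
})

test_that("infeasible currents raise informative errors, pipeline flags them", {
  isat <- girkstoich:::saturating_current(2.74)
  expect_error(infer_available_gbg(isat * 1.01, 2.74), "saturating")
  expect_error(infer_available_gbg(-1, 2.74), "i_total")
  expect_error(infer_available_ga(3, 2.74, 10.2), "exceeds")
  # boundary: basal equal to the zero-Galpha prediction gives ga = 0
  i_ga0 <- girkstoich:::saturating_current(2.74) *
    solve_evoked_state(gprotein_pool(
      density_to_concentration(2.74),
      density_to_concentration(10.2), 0
    ))$po_fraction
  ga <- infer_available_ga(i_ga0, 2.74, 10.2)
  expect_lt(ga$ga_total, 1e-6)
  # pipeline records infeasibility instead of failing
  bad <- tibble::tibble(group = "x", i_basal = 5, i_total = 40, i_bg = 3.49)
  est <- infer_stoichiometry(bad)
  expect_false(est$feasible)
  expect_match(est$note, "saturating")
  expect_error(
    infer_stoichiometry(tibble::tibble(i_basal = 2, i_total = 40)),
    "i_bg"
  )
})

test_that("density can be assumed from i_total when i_bg is missing", {
  est <- infer_stoichiometry(oocyte_groups[, c("group", "i_basal", "i_total")],
                             density_source = "from_itotal_ratio",
                             ibg_over_itotal = 2)
  expect_true(all(est$feasible))
  expect_equal(est$channel_density,
               channels_from_ibg(2 * oocyte_groups$i_total)$channel_density)
  # i_total backfilled from basal + evoked
  est2 <- infer_stoichiometry(
    oocyte_groups[, c("group", "i_basal", "i_evoked", "i_bg")]
  )
  expect_equal(est2$gbg_total, infer_stoichiometry(oocyte_groups)$gbg_total)
})

test_that("kd sweep keeps Gbetagamma per channel in the stable band", {
  sweep <- sensitivity_sweep(oocyte_groups, "kd_channel",
                             grid = c(5, 10, 25, 50, 75, 100))
  expect_true(all(sweep$feasible))
  # band edges are printed to one decimal; compare at that precision
  expect_true(all(sweep$gbg_per_channel >= 3 - 0.05 &
                    sweep$gbg_per_channel <= 4.2 + 0.05))
  # estimates vary smoothly and Gbg > Ga ordering holds everywhere
  expect_true(all(sweep$gbg_per_channel > sweep$ga_per_channel))
})

test_that("width sweep rescales totals smoothly, preserving ordering", {
  sweep <- sensitivity_sweep(oocyte_groups, "width", grid = c(1, 5, 10, 20))
  expect_true(all(sweep$feasible))
  expect_true(all(sweep$gbg_total > sweep$ga_total))
  for (g in unique(sweep$group)) {
    sub <- sweep[sweep$group == g, ]
    # ratios change smoothly (no sign flips, bounded range)
    expect_lt(diff(range(sub$gbg_per_channel)) / min(sub$gbg_per_channel), 1)
  }
})

test_that("zero intrinsic activity reproduces the plain graded estimate", {
  sweep <- sensitivity_sweep(oocyte_groups, "phi_intrinsic",
                             grid = c(1e-12, 0.05, 0.1))
  base <- infer_stoichiometry(oocyte_groups)
  sub0 <- sweep[sweep$value == 1e-12, ]
  expect_equal(sub0$gbg_total, base$gbg_total, tolerance = 1e-6)
  expect_equal(sub0$ga_total, base$ga_total, tolerance = 1e-6)
  # Gbetagamma-independent basal fraction grows as density falls
  sub10 <- sweep[sweep$value == 0.1, ]
  params10 <- gating_params(variant = "graded_intrinsic", phi = 0.9)
  frac_intrinsic <- vapply(seq_len(nrow(sub10)), function(i) {
    st <- solve_resting_state(
      gprotein_pool(
        density_to_concentration(sub10$channel_density[i]),
        density_to_concentration(sub10$gbg_total[i]),
        density_to_concentration(sub10$ga_total[i])
      ),
      params10
    )
    (1 - params10$phi) / st$po_fraction
  }, numeric(1))
  ord <- order(sub10$channel_density)
  expect_true(all(diff(frac_intrinsic[ord]) < 0))
})

test_that("sweep validation rejects bad grids", {
  expect_error(sensitivity_sweep(oocyte_groups, "kd_channel", numeric(0)),
               "non-empty")
  expect_error(sensitivity_sweep(oocyte_groups, "kd_channel", c(10, 5)),
               "increasing")
})
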