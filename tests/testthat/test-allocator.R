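test_that("analytic optimal ratio is a + b/k_syn", {
  # equal synthesis costs, no running cost -> ratio 1
  f0 <- cost_params(size_kDa = 40, atp_per_cycle = 0, cycle_rate = 0)
  h0 <- holdase_cost_params(size_kDa = 40)
  expect_equal(optimal_ratio_analytic(f0, h0, k_syn = 3), 1)
  # a = 1, b = 10/day at k_syn = 2/day -> 1 + 5 = 6
  f1 <- cost_params(size_kDa = 70, atp_per_cycle = 1,
                    cycle_rate = 35000 / 86400)
  h1 <- holdase_cost_params(size_kDa = 70)
  expect_equal(optimal_ratio_analytic(f1, h1, k_syn = 2), 6)
  # slow-synthesis limit: halving k_syn doubles the ratio
  r <- optimal_ratio_analytic(cost_params(), holdase_cost_params(),
                              c(1e-5, 2e-5))
  expect_equal(r[1] / r[2], 2, tolerance = 1e-3)
})

test_that("required holdase inverts the constraint exactly and is zero when foldases suffice", {
  fkin <- default_fkin; hkin <- default_hkin
  req <- requirement("proportional", u_o = 0.1)
  ld <- client_load(k_syn = 0.1, k_NU = 1, client_conc = 100)
  target <- target_u_free(req, ld$k_syn)
  for (mode in c("multiplicative", "exact")) {
    # generous foldase level: no holdases needed
    f_big <- 1e4 * ld$v_total / fkin$k_foldase_day
    expect_identical(required_holdase(f_big, ld, req, fkin, hkin, mode), 0)
    # tight foldase level: returned holdase puts U_free exactly on target
    f <- 3 * ld$v_total / fkin$k_foldase_day
    h <- required_holdase(f, ld, req, fkin, hkin, mode)
    expect_gt(h, 0)
    expect_equal(combined_u_free(ld, f, h, fkin, hkin, mode), target,
                 tolerance = 1e-12)
  }
  # modes agree in the 6D / far-from-saturation regime: target well below
  # both Kd and the foldase-only level, capacity well above the load
  ld2 <- client_load(k_syn = 0.01, k_NU = 1, client_conc = 100)
  f <- 50 * ld2$v_total / fkin$k_foldase_day
  h_m <- required_holdase(f, ld2, req, fkin, hkin, "multiplicative")
  h_e <- required_holdase(f, ld2, req, fkin, hkin, "exact")
  expect_gt(h_e, 10 * hkin$Kd)
  expect_lt(abs(h_m - h_e) / h_e, 0.15)
})

test_that("optimizer meets the constraint, satisfies the marginal condition, and matches the analytic ratio at slow growth", {
  cfg <- chap_config()
  for (mode in c("multiplicative", "exact")) {
    o <- optimize_allocation(1e-3, cfg, mode = mode)
    expect_gt(o$holdase_conc, 0)
    # constraint active at the optimum
    expect_equal(o$U_free, o$target, tolerance = 1e-9)
    expect_lt(o$marginal_residual, 1e-6)
  }
  # slow-growth, 6D, linear-MM regime: numeric ratio ~ Eq-11 unit-cost ratio
  o <- optimize_allocation(1e-3, cfg, mode = "multiplicative")
  expect_equal(o$ratio,
               optimal_ratio_analytic(cfg$cost_f, cfg$cost_h, 1e-3),
               tolerance = 0.05)
})

test_that("sweep reproduces the U-shaped total-chaperone curve with Fig-3 asymptotes", {
  sw <- sweep_synthesis_rates(chap_config())
  expect_s3_class(sw, "chap_sweep")
  expect_true(all(sw$feasible))
  expect_true(!is.unsorted(sw$k_syn))
  # single interior minimum of total chaperone investment (Goldilocks zone)
  d <- diff(log(sw$total_conc))
  expect_equal(sum(diff(sign(d)) != 0), 1)
  imin <- which.min(sw$total_conc)
  expect_true(imin > 1 && imin < nrow(sw))
  # foldase curve: flat at slow growth, ~linear at fast growth
  expect_lt(abs(asymptotic_slope(sw, "foldase", "slow")), 0.05)
  expect_equal(asymptotic_slope(sw, "foldase", "fast"), 1, tolerance = 0.1)
  # holdase curve rises inversely with k_syn at slow growth
  expect_lt(asymptotic_slope(sw, "holdase", "slow"), -0.9)
})

test_that("asymptotic slope fitting validates its window and recovers a planted power law", {
  fake <- tibble::tibble(k_syn = log_spaced(1e-2, 1e2, 21))
  fake$holdase_conc <- 5 * fake$k_syn^-0.7
  fake$foldase_conc <- 2 * fake$k_syn^0.3
  fake$total_conc <- fake$holdase_conc + fake$foldase_conc
  fake$feasible <- TRUE
  class(fake) <- c("chap_sweep", class(fake))
  expect_equal(asymptotic_slope(fake, "holdase", "slow"), -0.7,
               tolerance = 1e-9)
  expect_equal(asymptotic_slope(fake, "foldase", "fast"), 0.3,
               tolerance = 1e-9)
  narrow <- fake[fake$k_syn >= 0.5 & fake$k_syn <= 2, ]
  class(narrow) <- class(fake)
  expect_error(asymptotic_slope(narrow, "holdase", "slow"), "decade")
})

test_that("named variants modify the configuration as documented", {
  base <- chap_config()
  expect_equal(synthesis_cost(apply_variant(base, "size_x10")$cost_f), 35000)
  expect_equal(synthesis_cost(base$cost_f), 3500)

  fixed <- apply_variant(base, "fixed_requirement")
  expect_equal(target_u_free(fixed$req, c(1e-3, 1, 1e3)), rep(0.1, 3))

  perfect <- apply_variant(base, "perfect_foldase")
  expect_equal(running_cost_rate(perfect$cost_f, engaged_fraction = 0), 0)
  idle <- apply_variant(base, "idle_10pct")
  expect_equal(idle$cost_f$idle_activity_fraction, 0.1)

  expect_equal(apply_variant(base, "Kd_tight")$hkin$Kd, 0.01)
  expect_equal(apply_variant(base, "Kd_loose")$hkin$Kd, 1)
  expect_equal(apply_variant(base, "Kd_tight")$variant, "Kd_tight")
  expect_error(apply_variant(base, "warp_drive"))
})
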