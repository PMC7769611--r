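test_that("foldase flux saturates, half-saturates at Km, and matches hand evaluation", {
  kin <- default_fkin
  plateau <- kin$k_foldase_day * 2
  expect_equal(foldase_flux(1e9, 2, kin), plateau, tolerance = 1e-6)
  expect_equal(foldase_flux(kin$Km, 2, kin), plateau / 2)
  # plateau of 3 uM/day at U = 2 Km gives flux 3 / (1 + 1/2) = 2 uM/day
  kin3 <- foldase_kinetics(k_foldase = 3 / 86400, Km = 1)
  expect_equal(foldase_flux(2, 1, kin3), 2)
  expect_identical(foldase_flux(0, 2, kin), 0)
  expect_error(foldase_flux(-1, 2, kin), ">= 0")
})

test_that("steady-state pool rises 4-fold for a 2-fold load at 3x capacity and diverges at saturation", {
  kin <- default_fkin
  # capacity = 3 * load: pick foldase so that k_foldase_day * F = 3 * v
  ld1 <- client_load(k_syn = 1, k_NU = 0, client_conc = 100)
  f3 <- 3 * ld1$v_total / kin$k_foldase_day
  u1 <- steady_state_u(ld1, f3, kin)
  expect_equal(u1, kin$Km / 2)
  ld2 <- client_load(k_syn = 2, k_NU = 0, client_conc = 100)
  u2 <- steady_state_u(ld2, f3, kin)
  expect_equal(u2 / u1, 4)
  # vanishing load
  expect_equal(steady_state_u(client_load(0, 0, 100), 1, kin), 0)
  # at/over capacity the steady state does not exist
  f_at <- ld1$v_total / kin$k_foldase_day
  expect_error(steady_state_u(ld1, f_at, kin), "diverges")
  expect_error(steady_state_u(ld1, f_at * 0.5, kin), "deficit")
})

test_that("linear approximation bounds the exact pool with known error far from saturation", {
  kin <- default_fkin
  ld <- client_load(k_syn = 1, k_NU = 1, client_conc = 100)
  f10 <- 10 * ld$v_total / kin$k_foldase_day
  exact <- steady_state_u(ld, f10, kin)
  approxv <- linear_u(ld, f10, kin)
  expect_equal((exact - approxv) / approxv, 1 / 9, tolerance = 1e-12)
  f100 <- 100 * ld$v_total / kin$k_foldase_day
  expect_equal(linear_u(ld, f100, kin), steady_state_u(ld, f100, kin),
               tolerance = 0.011)
  expect_true(all(linear_u(ld, c(f10, f100), kin) <=
                    c(steady_state_u(ld, f10, kin),
                      steady_state_u(ld, f100, kin))))
  # explicit 1/foldase dependence and zero-load limit
  expect_equal(linear_u(ld, 2 * f10, kin), linear_u(ld, f10, kin) / 2)
  expect_equal(linear_u(client_load(0, 0, 100), f10, kin), 0)
  expect_error(linear_u(ld, 0, kin), "> 0")
})

test_that("steady state is strictly monotone in load and foldase level", {
  kin <- default_fkin
  f <- 1
  loads <- lapply(seq(0.1, 2, length.out = 12),
                  function(k) client_load(k, 1, 100))
  u <- vapply(loads, steady_state_u, numeric(1), foldase_conc = f, kin = kin)
  expect_true(all(diff(u) > 0))
  fs <- seq(0.5, 5, length.out = 12)
  ld <- client_load(1, 1, 100)
  u2 <- vapply(fs, function(ff) steady_state_u(ld, ff, kin), numeric(1))
  expect_true(all(diff(u2) < 0))
})

test_that("holdase partition conserves mass and matches an independent root-finder", {
  set.seed(7)
  n <- 1000
  U_tot <- 10^runif(n, -3, 2)
  H <- 10^runif(n, -3, 2.5)
  Kd <- 10^runif(n, -2, 1)
  for (i in seq_len(n)) {
    kin <- holdase_kinetics(Kd = Kd[i])
    p <- holdase_partition(U_tot[i], H[i], kin)
    expect_equal(p$U_free + p$U_bound, U_tot[i], tolerance = 1e-12)
    expect_true(p$U_free >= 0 && p$U_bound >= -1e-15)
    expect_true(p$U_bound <= H[i] * (1 + 1e-12))
  }
  # spot-check against bisection on a stratified subset
  idx <- seq(1, n, by = 25)
  for (i in idx) {
    kin <- holdase_kinetics(Kd = Kd[i])
    expect_equal(holdase_partition(U_tot[i], H[i], kin)$U_free,
                 oracle_u_free(U_tot[i], H[i], Kd[i]), tolerance = 1e-9)
  }
  # degenerate zeros return trivially
  expect_equal(holdase_partition(1, 0, default_hkin)$U_free, 1)
  expect_equal(holdase_partition(0, 5, default_hkin)$U_free, 0)
  # tight-binding limit: holdases fully loaded
  expect_equal(holdase_partition(1, 0.4, holdase_kinetics(Kd = 1e-12))$U_free,
               0.6, tolerance = 1e-9)
  # U_free strictly decreasing in holdase level
  u_seq <- holdase_partition(1, seq(0, 50, length.out = 20),
                             default_hkin)$U_free
  expect_true(all(diff(u_seq) < 0))
})

test_that("holdase partition keeps accuracy in the unsaturated regime (vs 6D)", {
  kin <- holdase_kinetics(Kd = 2)
  exact <- holdase_partition(0.1, 20, kin)$U_free
  expect_equal(exact, oracle_u_free(0.1, 20, 2), tolerance = 1e-12)
  # 6D approximation U_tot * Kd / H = 0.01 agrees within its error bound
  approx6d <- limiting_case_u(0.1, 20, kin, "6D")
  expect_equal(approx6d, 0.01)
  expect_lt(abs(approx6d - exact) / exact, (0.1 + 2) / 20)
})

test_that("limiting cases agree with the exact quadratic inside their regimes", {
  kin <- holdase_kinetics(Kd = 2)
  expect_equal(limiting_case_u(1, 20, kin, "6D"), 0.1)
  # 6C equals 6D up to 2 Kd / holdase when binding is loose
  for (h in c(50, 200, 1000)) {
    c6c <- limiting_case_u(0.01, h, kin, "6C")
    c6d <- limiting_case_u(0.01, h, kin, "6D")
    expect_lt(abs(c6d - c6c) / c6d, 2 * kin$Kd / h)
  }
  # out-of-regime tight-binding case is flagged
  expect_warning(limiting_case_u(1, 5, holdase_kinetics(Kd = 1e-4), "6B"),
                 "out of regime")

  # property sweep: each case within 10% of the exact root in its regime
  set.seed(11)
  n <- 1000
  for (i in seq_len(n)) {
    case <- sample(c("6A", "6B", "6D"), 1)
    Kd <- 10^runif(1, -2, 1)
    if (case == "6A") {            # holdase << U_tot & Kd
      U_tot <- 10^runif(1, -1, 1)
      H <- 0.01 * min(U_tot, Kd) * runif(1)
    } else if (case == "6B") {     # Kd << holdase & U_tot, holdase < U_tot
      U_tot <- 10^runif(1, -1, 1)
      H <- U_tot * runif(1, 0.1, 0.9)
      Kd <- 0.005 * min(H, U_tot - H)
    } else {                       # U_tot & Kd << holdase
      U_tot <- 10^runif(1, -2, 0)
      H <- 100 * max(U_tot, Kd) * 10^runif(1, 0, 1)
    }
    kin_i <- holdase_kinetics(Kd = Kd)
    exact <- holdase_partition(U_tot, H, kin_i)$U_free
    approx_i <- limiting_case_u(U_tot, H, kin_i, case)
    expect_lt(abs(approx_i - exact) / exact, 0.10)
  }
})

test_that("combined free level is multiplicative with unit log-sensitivities", {
  ld <- client_load(k_syn = 1, k_NU = 1, client_conc = 100)
  fkin <- default_fkin; hkin <- default_hkin
  u0 <- combined_u_free(ld, 1, 10, fkin, hkin, mode = "multiplicative")
  expect_equal(combined_u_free(ld, 2, 10, fkin, hkin, "multiplicative"),
               u0 / 2)
  expect_equal(combined_u_free(ld, 1, 20, fkin, hkin, "multiplicative"),
               u0 / 2)
  # finite differences recover dU/dF = -U/F and dU/dH = -U/H
  h <- 1e-6
  dF <- (combined_u_free(ld, 1 + h, 10, fkin, hkin, "multiplicative") -
           combined_u_free(ld, 1 - h, 10, fkin, hkin, "multiplicative")) /
    (2 * h)
  expect_equal(dF, -u0 / 1, tolerance = 1e-6)
  dH <- (combined_u_free(ld, 1, 10 + h, fkin, hkin, "multiplicative") -
           combined_u_free(ld, 1, 10 - h, fkin, hkin, "multiplicative")) /
    (2 * h)
  expect_equal(dH, -u0 / 10, tolerance = 1e-6)
  expect_error(combined_u_free(ld, 1, 0, fkin, hkin, "multiplicative"),
               "foldase-only")
})

test_that("multiplicative and exact modes agree far from saturation in the 6D regime", {
  set.seed(5)
  fkin <- default_fkin; hkin <- default_hkin
  for (i in 1:50) {
    ld <- client_load(k_syn = 10^runif(1, -2, 0), k_NU = 1,
                      client_conc = 10^runif(1, 1.5, 2.5))
    f <- 10^runif(1, 1, 2) * ld$v_total / fkin$k_foldase_day  # cap >= 10 v
    u_tot <- steady_state_u(ld, f, fkin)
    h <- 10 * max(u_tot, hkin$Kd) * 10^runif(1, 0, 1)
    mult <- combined_u_free(ld, f, h, fkin, hkin, "multiplicative")
    exact <- combined_u_free(ld, f, h, fkin, hkin, "exact")
    expect_lt(abs(mult - exact) / exact, 0.15)
  }
})
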