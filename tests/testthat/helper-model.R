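# shared fixtures: default kinetics and a reproducible drawer of random
# parameter sets for property-style tests

default_fkin <- foldase_kinetics()   # 0.1/s, Km 1 uM
default_hkin <- holdase_kinetics()   # Kd 2 uM

# random model/cost parameter sets spanning physiological ranges
draw_param_sets <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    Km = 10^runif(n, -0.5, 0.5),
    k_foldase = 10^runif(n, -1.5, -0.5),
    Kd = 10^runif(n, -0.5, 0.7),
    k_NU = 10^runif(n, -0.5, 0.5),
    client_conc = 10^runif(n, 1.5, 2.5),
    u_o = 10^runif(n, -1.5, -0.5),
    f_size = runif(n, 50, 100),
    h_size = runif(n, 20, 60),
    cycle_rate = 10^runif(n, -1.5, -0.5),
    k_syn = 10^runif(n, -2, 1)
  )
}

config_from_draw <- function(d) {
  chap_config(
    fkin = foldase_kinetics(d$k_foldase, d$Km),
    hkin = holdase_kinetics(d$Kd),
    cost_f = cost_params(size_kDa = d$f_size, cycle_rate = d$cycle_rate),
    cost_h = holdase_cost_params(size_kDa = d$h_size),
    req = requirement("proportional", u_o = d$u_o),
    k_NU = d$k_NU, client_conc = d$client_conc
  )
}

# independent root-finding oracle for the holdase binding equilibrium:
# solves U + H*U/(Kd + U) = U_tot by bisection, no quadratic involved
oracle_u_free <- function(U_tot, H, Kd) {
  if (U_tot == 0) return(0)
  f <- function(u) u + H * u / (Kd + u) - U_tot
  stats::uniroot(f, c(0, U_tot), tol = 1e-14 * max(U_tot, 1))$root
}
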