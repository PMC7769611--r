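#' Analytic optimal holdase:foldase ratio
#'
#' At a cost-efficient optimum the two chaperone classes are expressed in
#' proportion to their unit costs, `[holdase]/[foldase] =
#' c_foldase / c_holdase = a + b / k_syn`, with `a` the ratio of synthesis
#' costs and `b` the foldase running cost per day over the holdase
#' synthesis cost. In the slow-synthesis limit the running cost dominates
#' and the ratio grows as `b / k_syn`.
#'
#' @param cost_f,cost_h [cost_params()] for the foldase and holdase.
#' @param k_syn Turnover rate, 1/day (vectorized).
#' @param engaged_fraction Foldase engagement used for the running cost
#'   (default 1, always on).
#' @return Dimensionless ratio `[holdase]/[foldase]`.
#' @examples
#' optimal_ratio_analytic(cost_params(), holdase_cost_params(), k_syn = 1)
#' @export
optimal_ratio_analytic <- function(cost_f, cost_h, k_syn,
                                   engaged_fraction = 1) {
  c_syn_h <- synthesis_cost(cost_h)
  if (c_syn_h <= 0) abort("holdase synthesis cost must be > 0.")
  a <- synthesis_cost(cost_f) / c_syn_h
  b <- running_cost_rate(cost_f, engaged_fraction) * HOURS_PER_DAY / c_syn_h
  a + b / k_syn
}

#' Smallest holdase level meeting the unfoldedness requirement
#'
#' Given a foldase level, inverts the combined equilibrium for the holdase
#' concentration at which `U_free` just reaches the target. Returns 0 when
#' the foldases alone already meet it. In `"multiplicative"` mode the
#' inversion is `holdase = Kd * U_foldase_only / target`; in `"exact"` mode
#' the binding equilibrium gives `holdase_tot =
#' (U_tot - target) * (1 + Kd / target)`.
#'
#' @param foldase_conc Foldase concentration, uM.
#' @param load A [client_load()] (its `k_syn` sets the proportional target).
#' @param req A [requirement()].
#' @param fkin,hkin Kinetics objects.
#' @param mode `"multiplicative"` or `"exact"`.
#' @return Required holdase functional-unit concentration, uM.
#' @export
required_holdase <- function(foldase_conc, load, req, fkin, hkin,
                             mode = c("multiplicative", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(load, "client_load"), inherits(req, "requirement"))
  target <- target_u_free(req, load$k_syn)
  if (target <= 0) abort("requirement target must be > 0.")
  U_fo <- if (mode == "multiplicative") {
    linear_u(load, foldase_conc, fkin)
  } else {
    steady_state_u(load, foldase_conc, fkin)
  }
  if (U_fo <= target) return(0)
  if (mode == "multiplicative") {
    hkin$Kd * U_fo / target
  } else {
    (U_fo - target) * (1 + hkin$Kd / target)
  }
}

# total ATP cost density (ATP * uM over one turnover period) of an
# allocation; engagement is load/capacity when running cost is
# load-dependent (idle_activity_fraction < 1)
allocation_cost <- function(foldase_conc, holdase_conc, k_syn, load,
                            config) {
  engaged <- foldase_engagement(foldase_conc, load, config$fkin)
  cf <- unit_cost(config$cost_f, k_syn, engaged)$c_total
  cf * foldase_conc + synthesis_cost(config$cost_h) * holdase_conc
}

foldase_engagement <- function(foldase_conc, load, fkin) {
  pmin(1, load$v_total / (fkin$k_foldase_day * foldase_conc))
}

#' Cost-minimal chaperone allocation at one synthesis rate
#'
#' Minimizes the ATP cost density `c_foldase(k_syn) * [foldase] +
#' c_holdase * [holdase]` subject to `U_free <=` the unfoldedness target.
#' The holdase level is eliminated through [required_holdase()], reducing
#' the problem to a one-dimensional search over `log(foldase)` between the
#' saturation boundary and the foldase-only solution; the foldase-only
#' corner is compared explicitly. At an interior optimum the marginal
#' decrease in `U_free` per marginal ATP must be equal across the two
#' chaperone classes; `marginal_residual` reports the relative departure
#' from that condition (computed with central finite differences, using
#' marginal — not average — costs so load-dependent-engagement variants are
#' handled consistently).
#'
#' @param k_syn Synthesis rate, 1/day.
#' @param config A [chap_config()].
#' @param mode Equilibrium mode, `"exact"` (default) or
#'   `"multiplicative"`.
#' @param tol Relative tolerance of the line search.
#' @return A one-row tibble: `k_syn`, `foldase_conc`, `holdase_conc`,
#'   `total_conc`, `total_cost` (ATP*uM), `ratio` (holdase/foldase),
#'   `U_free`, `target`, `marginal_residual`, `mode`, `variant`,
#'   `feasible`.
#' @examples
#' optimize_allocation(1, chap_config())
#' @export
optimize_allocation <- function(k_syn, config,
                                mode = c("exact", "multiplicative"),
                                tol = 1e-10) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "chap_config"))
  if (k_syn <= 0) abort("`k_syn` must be > 0 (1/day).")
  load <- config_load(config, k_syn)
  v <- load$v_total
  kcat <- config$fkin$k_foldase_day
  Km <- config$fkin$Km
  target <- target_u_free(config$req, k_syn)
  if (v <= 0) abort("zero unfolding load: nothing to optimize.")

  f_min <- v / kcat                       # saturation boundary
  f_solo <- if (mode == "exact") {
    v * (Km / target + 1) / kcat          # foldase-only meets target
  } else {
    Km * v / (kcat * target)
  }
  f_lo <- max(f_min * (1 + 1e-9), f_solo * 1e-10)

  hold_of <- function(f) required_holdase(f, load, config$req,
                                          config$fkin, config$hkin, mode)
  cost_of <- function(f) allocation_cost(f, hold_of(f), k_syn, load, config)

  opt <- optimize(function(x) cost_of(exp(x)),
                  interval = c(log(f_lo), log(f_solo)), tol = tol)
  f_star <- exp(opt$minimum)
  h_star <- hold_of(f_star)
  c_star <- cost_of(f_star)

  # foldase-only corner (holdase = 0)
  c_corner <- allocation_cost(f_solo, 0, k_syn, load, config)
  if (c_corner < c_star) {
    f_star <- f_solo; h_star <- 0; c_star <- c_corner
  }

  resid <- if (h_star > 0) {
    marginal_residual(f_star, h_star, k_syn, load, config, mode)
  } else NA_real_

  u_free <- if (h_star > 0) {
    combined_u_free(load, f_star, h_star, config$fkin, config$hkin, mode)
  } else if (mode == "exact") {
    steady_state_u(load, f_star, config$fkin)
  } else {
    linear_u(load, f_star, config$fkin)
  }

  tibble::tibble(
    k_syn = k_syn, foldase_conc = f_star, holdase_conc = h_star,
    total_conc = f_star + h_star, total_cost = c_star,
    ratio = ifelse(f_star > 0, h_star / f_star, NA_real_),
    U_free = u_free, target = target, marginal_residual = resid,
    mode = mode, variant = config$variant, feasible = TRUE
  )
}

# relative departure from the equal-marginal-benefit-per-ATP condition,
# via central finite differences at the optimum
marginal_residual <- function(f, h, k_syn, load, config, mode,
                              h_rel = 1e-6) {
  u_of <- function(ff, hh)
    combined_u_free(load, ff, hh, config$fkin, config$hkin, mode)
  fcost_of <- function(ff) {
    engaged <- foldase_engagement(ff, load, config$fkin)
    unit_cost(config$cost_f, k_syn, engaged)$c_total * ff
  }
  dU_dF <- (u_of(f * (1 + h_rel), h) - u_of(f * (1 - h_rel), h)) /
    (2 * h_rel * f)
  dU_dH <- (u_of(f, h * (1 + h_rel)) - u_of(f, h * (1 - h_rel))) /
    (2 * h_rel * h)
  mc_f <- (fcost_of(f * (1 + h_rel)) - fcost_of(f * (1 - h_rel))) /
    (2 * h_rel * f)
  mc_h <- synthesis_cost(config$cost_h)
  abs((dU_dF / mc_f) / (dU_dH / mc_h) - 1)
}

#' Sweep the cost-minimal allocation across synthesis rates
#'
#' Runs [optimize_allocation()] on a log-spaced `k_syn` grid, producing the
#' optimal foldase and holdase expression curves. Slow synthesis rates
#' favour holdases (long protein lifetimes make foldase running costs
#' dominate), fast rates favour foldases, and the total chaperone
#' investment is U-shaped with a minimum in between (the "Goldilocks
#' zone"). Per-point failures are flagged, not fatal.
#'
#' @param config A [chap_config()].
#' @param k_syn_grid Synthesis rates in 1/day; default 61 log-spaced
#'   points over `[1e-3, 1e3]`.
#' @param mode Equilibrium mode passed to [optimize_allocation()].
#' @return A tibble of class `chap_sweep`, one row per grid point, sorted
#'   by `k_syn`, with the columns of [optimize_allocation()].
#' @examples
#' sw <- sweep_synthesis_rates(chap_config(),
#'                             k_syn_grid = log_spaced(1e-2, 1e2, 11))
#' @export
sweep_synthesis_rates <- function(config,
                                  k_syn_grid = log_spaced(1e-3, 1e3, 61),
                                  mode = c("exact", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "chap_config"))
  if (any(k_syn_grid <= 0)) abort("`k_syn_grid` must be positive.")
  k_syn_grid <- sort(k_syn_grid)
  rows <- purrr::map(k_syn_grid, function(k) {
    tryCatch(optimize_allocation(k, config, mode = mode),
             error = function(e) tibble::tibble(
               k_syn = k, foldase_conc = NA_real_, holdase_conc = NA_real_,
               total_conc = NA_real_, total_cost = NA_real_,
               ratio = NA_real_, U_free = NA_real_,
               target = target_u_free(config$req, k),
               marginal_residual = NA_real_, mode = mode,
               variant = config$variant, feasible = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chap_sweep", class(out))
  attr(out, "config") <- config
  out
}

#' Log-spaced grid
#'
#' @param from,to Positive endpoints.
#' @param n Number of points.
#' @return Numeric vector of `n` logarithmically spaced values.
#' @export
log_spaced <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 2)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Asymptotic log-log scaling slope of a sweep
#'
#' OLS slope of `log10(level)` against `log10(k_syn)` over the lowest
#' (`"slow"`) or highest (`"fast"`) decade of the sweep grid, where the
#' asymptotic scaling claims hold. Under the constant-running-cost model
#' the slow-growth slopes are -1 for holdases and 0 for foldases; in the
#' perfect-foldase (efficient chaperone buffer) limit both approach -1/2.
#'
#' @param sweep A `chap_sweep` from [sweep_synthesis_rates()].
#' @param which `"holdase"`, `"foldase"` or `"total"`.
#' @param regime `"slow"` or `"fast"`.
#' @return The fitted slope (dimensionless scalar).
#' @export
asymptotic_slope <- function(sweep, which = c("holdase", "foldase", "total"),
                             regime = c("slow", "fast")) {
  which <- match.arg(which)
  regime <- match.arg(regime)
  stopifnot(inherits(sweep, "chap_sweep") || is.data.frame(sweep))
  ks <- sweep$k_syn
  if (log10(max(ks) / min(ks)) < 1 - 1e-9)
    abort("sweep grid must span at least one decade.")
  window <- if (regime == "slow") c(min(ks), min(ks) * 10)
            else c(max(ks) / 10, max(ks))
  sub <- dplyr::filter(sweep, .data$k_syn >= window[1] * (1 - 1e-9),
                       .data$k_syn <= window[2] * (1 + 1e-9),
                       .data$feasible)
  if (nrow(sub) < 3)
    abort("fewer than 3 feasible sweep points in the regime decade.")
  y <- switch(which, holdase = sub$holdase_conc,
              foldase = sub$foldase_conc, total = sub$total_conc)
  if (any(y <= 0)) abort("non-positive levels in the regime: cannot take logs.")
  unname(coef(lm(log10(y) ~ log10(sub$k_syn)))[2])
}

#' Named sensitivity variants of the model configuration
#'
#' Each variant reproduces one of the model's sensitivity analyses:
#' * `"constant_run"` — baseline: always-on foldase ATPase.
#' * `"size_x10"` — foldase size 70 -> 700 kDa (synthesis 3,500 -> 35,000
#'   ATP), HSP60-like.
#' * `"idle_10pct"` — idle ATPase activity reduced to 10% of the engaged
#'   rate; running cost becomes load-dependent.
#' * `"perfect_foldase"` — zero ATPase activity when not folding (the
#'   efficient chaperone buffer limit).
#' * `"fixed_requirement"` — target `U_free` fixed at 100 nM instead of
#'   proportional to `k_syn`.
#' * `"Kd_tight"` — holdase binding tightened to `Kd = 10 nM`.
#' * `"Kd_loose"` — holdase binding loosened to `Kd = 1 uM`.
#'
#' @param config A [chap_config()] to modify.
#' @param variant Variant name (see above).
#' @return A new `chap_config` with the variant applied and labelled.
#' @examples
#' apply_variant(chap_config(), "perfect_foldase")
#' @export
apply_variant <- function(config,
                          variant = c("constant_run", "size_x10",
                                      "idle_10pct", "perfect_foldase",
                                      "fixed_requirement", "Kd_tight",
                                      "Kd_loose")) {
  stopifnot(inherits(config, "chap_config"))
  variant <- match.arg(variant)
  cfg <- config
  cfg$variant <- variant
  switch(variant,
    constant_run = {
      cfg$cost_f$idle_activity_fraction <- 1
    },
    size_x10 = {
      cfg$cost_f$size_kDa <- config$cost_f$size_kDa * 10
    },
    idle_10pct = {
      cfg$cost_f$idle_activity_fraction <- 0.1
    },
    perfect_foldase = {
      cfg$cost_f$idle_activity_fraction <- 0
    },
    fixed_requirement = {
      cfg$req <- requirement("fixed", u_o = config$req$u_o, u_fixed = 0.1)
    },
    Kd_tight = {
      cfg$hkin$Kd <- 0.01
    },
    Kd_loose = {
      cfg$hkin$Kd <- 1
    }
  )
  cfg
}
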