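#' One-time ATP cost of synthesizing a chaperone
#'
#' Chain length times the per-residue polymerization-and-proofreading cost:
#' `(size_kDa * 1000 / da_per_residue) * atp_per_residue`. With the default
#' 5 ATP/residue and 100 Da/residue a 70 kDa foldase costs 3,500 ATP. An
#' optional amino-acid surcharge (`aa_cost_per_residue`) can be added; it
#' raises absolute costs without changing the conclusions and is off by
#' default.
#'
#' @param p A [cost_params()].
#' @return Synthesis cost in ATP.
#' @export
synthesis_cost <- function(p) {
  stopifnot(inherits(p, "cost_params"))
  n_res <- p$size_kDa * 1000 / p$da_per_residue
  n_res * (p$atp_per_residue + p$aa_cost_per_residue)
}

#' ATPase running cost rate of a chaperone
#'
#' A foldase engaged with a client burns `atp_per_cycle * cycle_rate` ATP/s;
#' when idle it burns the fraction `idle_activity_fraction` of that. The
#' blended rate at a given engagement is
#' `atp_per_cycle * cycle_rate * (engaged + (1 - engaged) * idle) * 3600`
#' ATP/hour. Holdases (`atp_per_cycle = 0`) cost nothing to run. With the
#' default `idle_activity_fraction = 1` the rate is constant and
#' load-independent ("always on").
#'
#' @param p A [cost_params()].
#' @param engaged_fraction Fraction of time spent actively folding, in
#'   [0, 1]. Default 1.
#' @return Running cost in ATP/hour.
#' @export
running_cost_rate <- function(p, engaged_fraction = 1) {
  stopifnot(inherits(p, "cost_params"))
  if (any(engaged_fraction < 0) || any(engaged_fraction > 1))
    abort("`engaged_fraction` must be in [0, 1].")
  blend <- engaged_fraction + (1 - engaged_fraction) * p$idle_activity_fraction
  p$atp_per_cycle * p$cycle_rate * SECONDS_PER_HOUR * blend
}

#' Breakeven time of running cost against synthesis cost
#'
#' The run duration after which an always-on chaperone's cumulative ATPase
#' expenditure equals its one-time synthesis cost. For an HSP70-class
#' foldase (3,500 ATP to make, 1 ATP per ~10 s cycle) this is about 10
#' hours; an order-of-magnitude slower cycle at comparable ATP per kDa per
#' cycle (HSP60-class) stretches it to about 100 hours. Beyond the
#' breakeven, running — not making — dominates the chaperone budget.
#'
#' @param p A [cost_params()].
#' @return Breakeven time in hours; `Inf` for ATP-independent chaperones.
#' @export
breakeven_time <- function(p) {
  rate <- running_cost_rate(p, engaged_fraction = 1)
  if (rate == 0) return(Inf)
  synthesis_cost(p) / rate
}

#' Lifetime-integrated unit cost of one chaperone molecule
#'
#' A chaperone runs for its effective half-life, set by degradation and
#' dilution to `t = 1/k_syn` (chaperone turnover is taken equal to the
#' client turnover it serves). Its total cost is
#' `c_total = c_syn + c_run_rate * lifetime`; for holdases this is just the
#' synthesis cost.
#'
#' @param p A [cost_params()].
#' @param k_syn Turnover rate, 1/day (> 0).
#' @param engaged_fraction Fraction of time actively folding (default 1).
#' @return A one-row tibble (class `cost_breakdown`) with `c_syn` (ATP),
#'   `c_run_rate` (ATP/hour), `lifetime` (hours) and `c_total` (ATP).
#' @examples
#' unit_cost(cost_params(), k_syn = 1)
#' @export
unit_cost <- function(p, k_syn, engaged_fraction = 1) {
  stopifnot(inherits(p, "cost_params"))
  if (any(k_syn <= 0)) abort("`k_syn` must be > 0 (1/day).")
  c_syn <- synthesis_cost(p)
  rate <- running_cost_rate(p, engaged_fraction)
  lifetime <- HOURS_PER_DAY / k_syn
  out <- tibble::tibble(
    c_syn = c_syn, c_run_rate = rate, lifetime = lifetime,
    c_total = c_syn + rate * lifetime
  )
  class(out) <- c("cost_breakdown", class(out))
  out
}
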