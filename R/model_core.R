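#' Foldase folding flux
#'
#' Michaelis-Menten flux of the foldase circuit acting on free unfolded
#' client: `v = k_foldase * [foldase] / (1 + Km / [U_free])`. Saturates at
#' `k_foldase * [foldase]` and is half-maximal at `U_free = Km`.
#'
#' @param U_free Free unfolded client concentration, uM (vectorized).
#' @param foldase_conc Foldase concentration, uM.
#' @param kin [foldase_kinetics()].
#' @return Folding flux in uM/day.
#' @examples
#' kin <- foldase_kinetics(k_foldase = 0.1, Km = 1)
#' foldase_flux(1, 2, kin)  # half of the 2 uM plateau, per day
#' @export
foldase_flux <- function(U_free, foldase_conc, kin) {
  stopifnot(inherits(kin, "foldase_kinetics"))
  if (any(U_free < 0) || any(foldase_conc < 0))
    abort("`U_free` and `foldase_conc` must be >= 0.")
  ifelse(U_free == 0, 0,
         kin$k_foldase_day * foldase_conc / (1 + kin$Km / U_free))
}

#' Steady-state unfolded pool set by the foldases
#'
#' In steady state the folding flux balances the unfolding load
#' `v = v_syn + v_NU`, giving `U = Km / (capacity / v - 1)` with capacity
#' `k_foldase * [foldase]`. The pool diverges as the load approaches
#' capacity: this is the overflow regime where unprocessed protein piles up
#' and aggregation risk rises.
#'
#' @param load A [client_load()].
#' @param foldase_conc Foldase concentration, uM.
#' @param kin [foldase_kinetics()].
#' @return Total unfolded concentration `U_tot` in uM.
#' @examples
#' ld <- client_load(k_syn = 1, k_NU = 1, client_conc = 100)
#' steady_state_u(ld, foldase_conc = 1, kin = foldase_kinetics())
#' @export
steady_state_u <- function(load, foldase_conc, kin) {
  stopifnot(inherits(load, "client_load"), inherits(kin, "foldase_kinetics"))
  if (any(foldase_conc < 0)) abort("`foldase_conc` must be >= 0.")
  v <- load$v_total
  capacity <- kin$k_foldase_day * foldase_conc
  if (v == 0) return(rep_len(0, length(foldase_conc)))
  if (any(v >= capacity)) {
    deficit <- v - min(capacity)
    abort(sprintf(
      paste0("unfolding load (%.4g uM/day) meets or exceeds foldase ",
             "capacity (%.4g uM/day): steady state diverges ",
             "(deficit %.4g uM/day); raise foldase_conc"),
      v, min(capacity), deficit))
  }
  kin$Km / (capacity / v - 1)
}

#' Linear (far-from-saturation) approximation to the unfolded pool
#'
#' When capacity greatly exceeds the load the steady state simplifies to
#' `U ~ Km * v / (k_foldase * [foldase])`: the pool is proportional to load
#' and inversely proportional to foldase level. Always a lower bound on the
#' exact steady state.
#'
#' @inheritParams steady_state_u
#' @return Approximate unfolded concentration in uM.
#' @export
linear_u <- function(load, foldase_conc, kin) {
  stopifnot(inherits(load, "client_load"), inherits(kin, "foldase_kinetics"))
  if (any(foldase_conc <= 0))
    abort("`foldase_conc` must be > 0 for the linear approximation.")
  kin$Km * load$v_total / (kin$k_foldase_day * foldase_conc)
}

#' Partition the unfolded pool between free and holdase-bound states
#'
#' Solves the binding equilibrium `Kd = [U][holdase]/[U:holdase]` under the
#' two conservation constraints `U_tot = U_free + U_bound` and
#' `holdase_tot = holdase_free + U_bound`. With `a = Kd * U_tot` and
#' `b = Kd + holdase_tot - U_tot`, the physical root of the resulting
#' quadratic is evaluated in whichever of the two algebraically equivalent
#' forms `2 a / (b + sqrt(b^2 + 4 a))` (for `b >= 0`, accurate when
#' holdases are in excess or binding is tight) and
#' `(-b + sqrt(b^2 + 4 a)) / 2` (for `b < 0`, accurate when the unfolded
#' pool exceeds the holdase capacity) avoids subtractive cancellation.
#'
#' @param U_tot Total unfolded concentration, uM.
#' @param holdase_conc Total holdase functional-unit concentration, uM.
#' @param kin [holdase_kinetics()].
#' @return A tibble with columns `U_free`, `U_bound` (uM). Rows follow the
#'   vectorized inputs.
#' @examples
#' holdase_partition(1, 20, holdase_kinetics(Kd = 2))
#' @export
holdase_partition <- function(U_tot, holdase_conc, kin) {
  stopifnot(inherits(kin, "holdase_kinetics"))
  if (any(U_tot < 0) || any(holdase_conc < 0))
    abort("`U_tot` and `holdase_conc` must be >= 0.")
  n <- max(length(U_tot), length(holdase_conc))
  U_tot <- rep_len(U_tot, n)
  holdase_conc <- rep_len(holdase_conc, n)
  a <- kin$Kd * U_tot
  b <- kin$Kd + holdase_conc - U_tot
  disc <- sqrt(b^2 + 4 * a)
  U_free <- ifelse(U_tot == 0, 0,
            ifelse(holdase_conc == 0, U_tot,
            ifelse(b >= 0, 2 * a / (b + disc), (disc - b) / 2)))
  U_free <- pmin(U_free, U_tot)
  tibble::tibble(U_free = U_free, U_bound = U_tot - U_free)
}

#' Limiting-case closed forms of the holdase equilibrium
#'
#' The exact quadratic has three informative limits, labelled by the
#' supplementary panels they correspond to:
#' * `"6A"` scarce holdases (`holdase << U_tot` and `Kd`): `U_free = U_tot`.
#' * `"6B"` tight binding (`Kd << holdase` and `U_tot`): holdases are fully
#'   loaded, `U_free = U_tot - holdase_tot`.
#' * `"6C"` low unfoldedness (`U_tot << holdase`):
#'   `U_free = U_tot/2 * (1 + (Kd - holdase)/(Kd + holdase))`.
#' * `"6D"` low unfoldedness and loose binding (`U_tot` and
#'   `Kd << holdase`): `U_free = U_tot * Kd / holdase` — the
#'   physiologically typical regime, where holdases are mostly client-free.
#'
#' No regime policing is done: the caller picks the case; 6B is flagged
#' when evaluated outside its regime (negative result).
#'
#' @inheritParams holdase_partition
#' @param case One of `"6A"`, `"6B"`, `"6C"`, `"6D"`.
#' @return Approximate `U_free` in uM.
#' @export
limiting_case_u <- function(U_tot, holdase_conc, kin,
                            case = c("6D", "6A", "6B", "6C")) {
  stopifnot(inherits(kin, "holdase_kinetics"))
  case <- match.arg(case)
  if (any(U_tot < 0) || any(holdase_conc < 0))
    abort("`U_tot` and `holdase_conc` must be >= 0.")
  out <- switch(case,
    "6A" = U_tot + 0 * holdase_conc,
    "6B" = U_tot - holdase_conc,
    "6C" = U_tot / 2 * (1 + (kin$Kd - holdase_conc) /
                            (kin$Kd + holdase_conc)),
    "6D" = U_tot * kin$Kd / holdase_conc
  )
  if (case == "6B" && any(out < 0))
    warn("case 6B evaluated with holdase >= U_tot: negative U_free is out of regime")
  out
}

#' Combined free unfolded level under foldases and holdases
#'
#' Foldases set the size of the unfolded pool; holdases set the fraction of
#' that pool left free. In the typical regime the two factors are
#' multiplicative: `U_free = Km * v / (k_foldase * [foldase]) *
#' Kd / [holdase]`. The `"exact"` mode instead solves the foldase steady
#' state and then the full binding quadratic sequentially (the foldase
#' circuit equilibrates fast relative to holdase buffering, so no coupled
#' dynamic solve is needed).
#'
#' @param load A [client_load()].
#' @param foldase_conc,holdase_conc Allocation, uM.
#' @param fkin [foldase_kinetics()]; `hkin` [holdase_kinetics()].
#' @param hkin Holdase kinetics.
#' @param mode `"multiplicative"` (default) or `"exact"`.
#' @return `U_free` in uM.
#' @examples
#' ld <- client_load(k_syn = 1)
#' combined_u_free(ld, 1, 10, foldase_kinetics(), holdase_kinetics())
#' @export
combined_u_free <- function(load, foldase_conc, holdase_conc, fkin, hkin,
                            mode = c("multiplicative", "exact")) {
  mode <- match.arg(mode)
  if (mode == "multiplicative") {
    if (any(holdase_conc <= 0))
      abort(paste0("multiplicative mode needs holdase_conc > 0; ",
                   "for a foldase-only system use steady_state_u()/linear_u()"))
    linear_u(load, foldase_conc, fkin) * hkin$Kd / holdase_conc
  } else {
    U_tot <- steady_state_u(load, foldase_conc, fkin)
    holdase_partition(U_tot, holdase_conc, hkin)$U_free
  }
}
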