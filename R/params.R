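#' Foldase Michaelis-Menten kinetics
#'
#' Kinetic constants for the ATP-dependent foldase circuit. Foldases are
#' saturable and modelled as an enzyme acting on unfolded client protein:
#' the folding flux is `k_foldase * [foldase] / (1 + Km / [U_free])`.
#'
#' @param k_foldase Per-foldase catalytic rate when saturated, in 1/s.
#'   Default 0.1/s, i.e. one ~10 s ATPase cycle per folding attempt
#'   (HSP70-class).
#' @param Km Michaelis constant for unfolded client, in uM.
#'
#' @return An object of class `foldase_kinetics`: a list with `k_foldase`
#'   (1/s), `Km` (uM), and `k_foldase_day` (1/day, converted once here so
#'   downstream code works in day units throughout).
#' @examples
#' foldase_kinetics()
#' foldase_kinetics(k_foldase = 0.01, Km = 5)
#' @export
foldase_kinetics <- function(k_foldase = 0.1, Km = 1) {
  stopifnot(is.numeric(k_foldase), length(k_foldase) == 1,
            is.numeric(Km), length(Km) == 1)
  if (k_foldase <= 0) abort("`k_foldase` must be > 0 (1/s).")
  if (Km <= 0) abort("`Km` must be > 0 (uM).")
  structure(
    list(k_foldase = k_foldase, Km = Km,
         k_foldase_day = k_foldase * SECONDS_PER_DAY),
    class = "foldase_kinetics"
  )
}

#' Holdase binding equilibrium constants
#'
#' Holdases bind unfolded client protein reversibly and consume no ATP.
#' Concentrations refer to the functional (possibly multimeric) unit; a
#' monomer-to-unit stoichiometry is carried along for bookkeeping when
#' abundances are reported per monomer.
#'
#' @param Kd Dissociation constant of the holdase functional unit for
#'   unfolded client, in uM. Default 2 uM (small-HSP range).
#' @param monomers_per_unit Monomers per functional unit (default 1).
#'
#' @return An object of class `holdase_kinetics`.
#' @examples
#' holdase_kinetics()
#' holdase_kinetics(Kd = 0.01) # tight binding
#' @export
holdase_kinetics <- function(Kd = 2, monomers_per_unit = 1) {
  stopifnot(is.numeric(Kd), length(Kd) == 1)
  if (Kd <= 0) abort("`Kd` must be > 0 (uM).")
  if (monomers_per_unit < 1) abort("`monomers_per_unit` must be >= 1.")
  structure(list(Kd = Kd, monomers_per_unit = monomers_per_unit),
            class = "holdase_kinetics")
}

#' Client protein load
#'
#' The proteome-side fluxes feeding the unfolded pool: newly synthesized
#' protein arrives at `v_syn = k_syn * client_conc` and natively folded
#' protein unfolds spontaneously at `v_NU = k_NU * client_conc`.
#'
#' @param k_syn Proteome synthesis/turnover rate constant, 1/day. Its
#'   inverse sets the effective protein half-life.
#' @param k_NU Spontaneous unfolding rate constant of native protein,
#'   1/day (proteins unfold over hours to days).
#' @param client_conc Total foldase-dependent client concentration, uM.
#'
#' @return An object of class `client_load` with the rate constants and the
#'   derived fluxes `v_syn`, `v_NU`, `v_total` (uM/day).
#' @examples
#' client_load(k_syn = 1)
#' @export
client_load <- function(k_syn = 1, k_NU = 1, client_conc = 100) {
  stopifnot(is.numeric(k_syn), is.numeric(k_NU), is.numeric(client_conc))
  if (k_syn < 0 || k_NU < 0 || client_conc < 0)
    abort("`k_syn`, `k_NU` and `client_conc` must all be >= 0.")
  structure(
    list(k_syn = k_syn, k_NU = k_NU, client_conc = client_conc,
         v_syn = k_syn * client_conc, v_NU = k_NU * client_conc,
         v_total = (k_syn + k_NU) * client_conc),
    class = "client_load"
  )
}

#' Per-molecule chaperone cost parameters
#'
#' Chaperone costs split into a one-time synthesis cost, proportional to
#' chain length (5 ATP per residue polymerized and proofread), and a
#' running cost for ATP-consuming foldases. Holdases have
#' `atp_per_cycle = 0` and therefore no running cost.
#'
#' @param size_kDa Chaperone mass in kDa (70 for an HSP70-class foldase).
#' @param atp_per_residue ATP spent per amino acid polymerized (default 5).
#' @param da_per_residue Average residue mass in Da (default 100, making a
#'   70 kDa chain cost exactly 3,500 ATP).
#' @param atp_per_cycle ATP consumed per catalytic cycle (0 for holdases).
#' @param cycle_rate Catalytic cycles per second when engaged, 1/s.
#' @param idle_activity_fraction Fraction of the engaged ATPase rate that
#'   is still spent when the chaperone is not folding a client, in [0, 1].
#'   1 means the running cost is constant and load-independent ("always
#'   on"); 0 is the perfect-foldase limit.
#' @param aa_cost_per_residue Optional extra ATP-equivalent surcharge per
#'   residue for the amino acids themselves (default 0, excluded).
#'
#' @return An object of class `cost_params`.
#' @seealso [synthesis_cost()], [running_cost_rate()], [breakeven_time()]
#' @examples
#' cost_params()                     # HSP70-like foldase
#' cost_params(size_kDa = 40, atp_per_cycle = 0)  # holdase
#' @export
cost_params <- function(size_kDa = 70, atp_per_residue = 5,
                        da_per_residue = 100, atp_per_cycle = 1,
                        cycle_rate = 0.1, idle_activity_fraction = 1,
                        aa_cost_per_residue = 0) {
  if (size_kDa < 0) abort("`size_kDa` must be >= 0.")
  if (da_per_residue <= 0) abort("`da_per_residue` must be > 0.")
  if (atp_per_cycle < 0 || cycle_rate < 0)
    abort("`atp_per_cycle` and `cycle_rate` must be >= 0.")
  if (idle_activity_fraction < 0 || idle_activity_fraction > 1)
    abort("`idle_activity_fraction` must be in [0, 1].")
  structure(
    list(size_kDa = size_kDa, atp_per_residue = atp_per_residue,
         da_per_residue = da_per_residue, atp_per_cycle = atp_per_cycle,
         cycle_rate = cycle_rate,
         idle_activity_fraction = idle_activity_fraction,
         aa_cost_per_residue = aa_cost_per_residue),
    class = "cost_params"
  )
}

#' Holdase cost parameters
#'
#' Convenience wrapper: a 40 kDa ATP-independent functional unit.
#' @inheritParams cost_params
#' @return A `cost_params` object with `atp_per_cycle = 0`.
#' @export
holdase_cost_params <- function(size_kDa = 40, atp_per_residue = 5,
                                da_per_residue = 100,
                                aa_cost_per_residue = 0) {
  cost_params(size_kDa = size_kDa, atp_per_residue = atp_per_residue,
              da_per_residue = da_per_residue, atp_per_cycle = 0,
              cycle_rate = 0, idle_activity_fraction = 0,
              aa_cost_per_residue = aa_cost_per_residue)
}

#' Unfoldedness requirement
#'
#' The constraint the chaperone system must meet. In `proportional` mode
#' the tolerated free unfolded level scales with turnover,
#' `U_free <= u_o * k_syn`: a protein that lives twice as long must be
#' kept twice as folded so that its total unfolded dwell time over its
#' lifetime stays constant. In `fixed` mode the target is a constant
#' concentration regardless of synthesis rate.
#'
#' @param mode `"proportional"` (default) or `"fixed"`.
#' @param u_o Dwell-time budget in uM*day (default 0.1, i.e. 100 nM*day).
#' @param u_fixed Fixed target in uM (default 0.1, i.e. 100 nM).
#'
#' @return An object of class `requirement`.
#' @examples
#' target_u_free(requirement(), k_syn = 1)       # 0.1 uM
#' target_u_free(requirement("fixed"), k_syn = 1)
#' @export
requirement <- function(mode = c("proportional", "fixed"), u_o = 0.1,
                        u_fixed = 0.1) {
  mode <- match.arg(mode)
  if (u_o <= 0 || u_fixed <= 0) abort("requirement targets must be > 0.")
  structure(list(mode = mode, u_o = u_o, u_fixed = u_fixed),
            class = "requirement")
}

#' Target free unfolded concentration implied by a requirement
#'
#' @param req A [requirement()].
#' @param k_syn Synthesis rate, 1/day (vectorized).
#' @return Target `U_free` in uM.
#' @export
target_u_free <- function(req, k_syn) {
  stopifnot(inherits(req, "requirement"))
  if (req$mode == "proportional") req$u_o * k_syn
  else rep_len(req$u_fixed, length(k_syn))
}

#' Full model configuration
#'
#' Bundles kinetics, load constants, costs and the unfoldedness requirement
#' into one object consumed by the allocator and pipeline. `k_syn` is left
#' out on purpose: it is the independent variable of every sweep.
#'
#' @param fkin [foldase_kinetics()].
#' @param hkin [holdase_kinetics()].
#' @param cost_f Foldase [cost_params()].
#' @param cost_h Holdase [cost_params()] (ATP-independent).
#' @param req [requirement()].
#' @param k_NU Spontaneous unfolding rate, 1/day.
#' @param client_conc Total client concentration, uM.
#' @param variant Variant label attached to downstream results.
#'
#' @return An object of class `chap_config`.
#' @seealso [apply_variant()] for the named sensitivity variants.
#' @export
chap_config <- function(fkin = foldase_kinetics(),
                        hkin = holdase_kinetics(),
                        cost_f = cost_params(),
                        cost_h = holdase_cost_params(),
                        req = requirement(),
                        k_NU = 1, client_conc = 100,
                        variant = "constant_run") {
  stopifnot(inherits(fkin, "foldase_kinetics"),
            inherits(hkin, "holdase_kinetics"),
            inherits(cost_f, "cost_params"),
            inherits(cost_h, "cost_params"),
            inherits(req, "requirement"))
  if (cost_h$atp_per_cycle != 0)
    abort("holdases are ATP-independent: `cost_h$atp_per_cycle` must be 0.")
  if (k_NU < 0 || client_conc <= 0)
    abort("`k_NU` must be >= 0 and `client_conc` > 0.")
  structure(
    list(fkin = fkin, hkin = hkin, cost_f = cost_f, cost_h = cost_h,
         req = req, k_NU = k_NU, client_conc = client_conc,
         variant = variant),
    class = "chap_config"
  )
}

#' @export
print.chap_config <- function(x, ...) {
  cat("<chap_config> variant:", x$variant, "\n")
  cat(sprintf("  foldase: k = %.3g/s, Km = %.3g uM, %g kDa, idle ATPase %.0f%%\n",
              x$fkin$k_foldase, x$fkin$Km, x$cost_f$size_kDa,
              100 * x$cost_f$idle_activity_fraction))
  cat(sprintf("  holdase: Kd = %.3g uM, %g kDa\n",
              x$hkin$Kd, x$cost_h$size_kDa))
  cat(sprintf("  load: k_NU = %.3g/day, clients = %g uM\n",
              x$k_NU, x$client_conc))
  cat(sprintf("  requirement: %s (u_o = %g uM*day, u_fixed = %g uM)\n",
              x$req$mode, x$req$u_o, x$req$u_fixed))
  invisible(x)
}

#' Build the client load at a given synthesis rate from a configuration
#'
#' @param config A [chap_config()].
#' @param k_syn Synthesis rate, 1/day.
#' @return A [client_load()].
#' @export
config_load <- function(config, k_syn) {
  stopifnot(inherits(config, "chap_config"))
  client_load(k_syn = k_syn, k_NU = config$k_NU,
              client_conc = config$client_conc)
}
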