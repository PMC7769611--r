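# run code under a named RNG stream derived from one user seed, restoring
# the caller's RNG state afterwards; stream seeds stay below 2^31
with_stream_seed <- function(seed, stream_id, code) {
  if (is.null(seed) || is.na(seed)) abort("a `seed` is required.")
  sub <- (as.double(seed) %% 2147483647) * 48271 + stream_id * 1009
  sub <- as.integer(sub %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub)
  force(code)
}

#' Configuration of the cross-species abundance generator
#'
#' Describes a synthetic abundance-versus-rate table with the statistical
#' structure the scaling fits assume: a power law in rate with lognormal
#' (multiplicative) scatter, optionally one planted, flagged outlier.
#'
#' @param n_samples Number of samples/species (>= 3; default 6, a typical
#'   cross-species panel size).
#' @param true_slope Generating log-log slope (default -1, the holdase
#'   prediction at slow growth).
#' @param intercept_log10 log10 abundance at rate = 1 (default 1).
#' @param noise_sigma_log10 SD of the log10-normal scatter (default 0.3,
#'   i.e. ~2-fold typical deviation, a realistic proteomic spread).
#' @param rate_min Smallest rate (default 1, arbitrary units).
#' @param rate_decades Decades of rate covered log-uniformly (default 3,
#'   a mouse-to-large-mammal span of basal metabolic rates).
#' @param chaperone_class Class label stamped on the rows.
#' @param outlier `NULL`, or `list(index =, displacement_log10 =)` to
#'   displace one sample off the power law and flag it.
#' @param seed Mandatory integer seed.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_samples = 6, true_slope = -1,
                             intercept_log10 = 1, noise_sigma_log10 = 0.3,
                             rate_min = 1, rate_decades = 3,
                             chaperone_class = "holdase", outlier = NULL,
                             seed = NULL) {
  if (n_samples < 3) abort("`n_samples` must be >= 3.")
  if (noise_sigma_log10 < 0) abort("`noise_sigma_log10` must be >= 0.")
  if (rate_min <= 0 || rate_decades <= 0)
    abort("`rate_min` and `rate_decades` must be > 0.")
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  if (!is.null(outlier)) {
    if (!all(c("index", "displacement_log10") %in% names(outlier)))
      abort("`outlier` needs fields `index` and `displacement_log10`.")
    if (outlier$index < 1 || outlier$index > n_samples)
      abort("`outlier$index` out of range.")
  }
  structure(
    list(n_samples = n_samples, true_slope = true_slope,
         intercept_log10 = intercept_log10,
         noise_sigma_log10 = noise_sigma_log10, rate_min = rate_min,
         rate_decades = rate_decades, chaperone_class = chaperone_class,
         outlier = outlier, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic cross-species abundance table
#'
#' Rates are drawn log-uniformly over the configured range and abundances
#' follow `log10(abundance) = intercept + slope * log10(rate) + eps`,
#' `eps ~ Normal(0, sigma)` — i.e. a power law with lognormal scatter,
#' emulating chaperone levels across species of differing metabolic rate.
#' Output is byte-identical for identical configuration (the seed is part
#' of the configuration).
#'
#' @param cfg A [generator_config()].
#' @return A tibble with columns `sample_id`, `rate`, `chaperone_class`,
#'   `abundance`, `outlier_flag` — the schema [fit_loglog()] consumes.
#' @examples
#' gen_abundance_table(generator_config(seed = 42))
#' @export
gen_abundance_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_stream_seed(cfg$seed, 1L, {
    lrate <- log10(cfg$rate_min) + runif(cfg$n_samples) * cfg$rate_decades
    eps <- if (cfg$noise_sigma_log10 > 0)
      rnorm(cfg$n_samples, 0, cfg$noise_sigma_log10) else numeric(cfg$n_samples)
    labund <- cfg$intercept_log10 + cfg$true_slope * lrate + eps
    flag <- rep(FALSE, cfg$n_samples)
    if (!is.null(cfg$outlier)) {
      i <- cfg$outlier$index
      labund[i] <- labund[i] + cfg$outlier$displacement_log10
      flag[i] <- TRUE
    }
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(cfg$n_samples)),
      rate = 10^lrate,
      chaperone_class = cfg$chaperone_class,
      abundance = 10^labund,
      outlier_flag = flag
    )
  })
}

#' Configuration of the aging-trajectory generator
#'
#' Emulates chaperone proteomics over adult aging: the bulk protein
#' synthesis rate falls 15- to 30-fold across adulthood while, along the
#' cost-efficient path, holdases rise roughly in inverse proportion and
#' foldases stay comparatively flat.
#'
#' @param n_timepoints Number of ages sampled (default 8).
#' @param synthesis_fold_drop Total fold-decrease in `k_syn` from the
#'   first to the last timepoint (>= 1; default 20, mid-range of the
#'   observed 15-30-fold).
#' @param k_syn_start Young-adult synthesis rate, 1/day (default 0.25,
#'   i.e. bulk protein half-lives of a few days).
#' @param holdase_classes,foldase_classes Named numeric vectors: class
#'   labels with baseline abundance multipliers applied to the model's
#'   optimal level.
#' @param noise_sigma_log10 SD of multiplicative log10-normal noise
#'   (default 0.2).
#' @param seed Mandatory integer seed.
#' @return An `aging_config` object.
#' @export
aging_config <- function(n_timepoints = 8, synthesis_fold_drop = 20,
                         k_syn_start = 0.25,
                         holdase_classes = c("sip-1" = 1, "hsp-16" = 0.5),
                         foldase_classes = c("HSP70" = 1, "HSP60" = 0.5),
                         noise_sigma_log10 = 0.2, seed = NULL) {
  if (n_timepoints < 2) abort("`n_timepoints` must be >= 2.")
  if (synthesis_fold_drop < 1) abort("`synthesis_fold_drop` must be >= 1.")
  if (k_syn_start <= 0) abort("`k_syn_start` must be > 0.")
  if (noise_sigma_log10 < 0) abort("`noise_sigma_log10` must be >= 0.")
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  structure(
    list(n_timepoints = n_timepoints,
         synthesis_fold_drop = synthesis_fold_drop,
         k_syn_start = k_syn_start, holdase_classes = holdase_classes,
         foldase_classes = foldase_classes,
         noise_sigma_log10 = noise_sigma_log10, seed = as.integer(seed)),
    class = "aging_config"
  )
}

#' Generate a synthetic aging trajectory from a model sweep
#'
#' `k_syn` declines geometrically by `synthesis_fold_drop` across the
#' timepoints; each chaperone class tracks the sweep's optimal level at
#' that `k_syn` (log-log interpolated), scaled by its baseline multiplier,
#' with multiplicative lognormal noise. The "truth" is thus the model's
#' own cost-efficient path — generator and analyzer share no fitted code.
#'
#' @param cfg An [aging_config()].
#' @param model_sweep A `chap_sweep` from [sweep_synthesis_rates()] whose
#'   grid covers the implied `k_syn` range.
#' @return A tibble with `age_index`, `k_syn`, `chaperone_class`,
#'   `class_type` (`"holdase"`/`"foldase"`) and `abundance`.
#' @examples
#' sw <- sweep_synthesis_rates(chap_config(),
#'                             k_syn_grid = log_spaced(1e-3, 1e2, 26))
#' gen_aging_trajectory(aging_config(seed = 7), sw)
#' @export
gen_aging_trajectory <- function(cfg, model_sweep) {
  stopifnot(inherits(cfg, "aging_config"))
  sw <- dplyr::filter(model_sweep, .data$feasible)
  k_end <- cfg$k_syn_start / cfg$synthesis_fold_drop
  ks <- cfg$k_syn_start *
    cfg$synthesis_fold_drop^(-(seq_len(cfg$n_timepoints) - 1) /
                               (cfg$n_timepoints - 1))
  # interpolate each level on log-log axes over the sweep points where it
  # is positive (the optimum can sit at the foldase-only corner elsewhere)
  interp <- function(level, label) {
    pos <- level > 0
    if (sum(pos) < 2 ||
        min(sw$k_syn[pos]) > k_end * (1 + 1e-9) ||
        max(sw$k_syn[pos]) < cfg$k_syn_start * (1 - 1e-9))
      abort(sprintf(
        paste0("sweep coverage gap for %s: need k_syn in [%.3g, %.3g], ",
               "positive levels span [%.3g, %.3g]"),
        label, k_end, cfg$k_syn_start,
        if (any(pos)) min(sw$k_syn[pos]) else NA,
        if (any(pos)) max(sw$k_syn[pos]) else NA))
    10^stats::approx(log10(sw$k_syn[pos]), log10(level[pos]),
                     xout = log10(ks), rule = 1)$y
  }
  hold_level <- interp(sw$holdase_conc, "holdase")
  fold_level <- interp(sw$foldase_conc, "foldase")
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(class_type = "holdase",
                       chaperone_class = names(cfg$holdase_classes)),
    tidyr::expand_grid(class_type = "foldase",
                       chaperone_class = names(cfg$foldase_classes))
  )
  with_stream_seed(cfg$seed, 2L, {
    purrr::pmap_dfr(grid, function(class_type, chaperone_class) {
      base <- if (class_type == "holdase")
        cfg$holdase_classes[[chaperone_class]]
      else cfg$foldase_classes[[chaperone_class]]
      level <- if (class_type == "holdase") hold_level else fold_level
      eps <- if (cfg$noise_sigma_log10 > 0)
        rnorm(length(ks), 0, cfg$noise_sigma_log10) else numeric(length(ks))
      tibble::tibble(
        age_index = seq_along(ks), k_syn = ks,
        chaperone_class = chaperone_class, class_type = class_type,
        abundance = base * level * 10^eps
      )
    })
  })
}
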