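#' Configuration of one simulated population
#'
#' Encodes the pace-of-life contrast the simulator emulates: annual adult
#' survival sets the lifespan distribution (fast populations die younger),
#' the base clutch sets mean investment, and the oscillatory components
#' inject known reproductive investment curves — a short-term Nyquist
#' alternation (wavelength exactly 2 years, the carry-over analogue) and a
#' long-term wave (wavelength drawn from `long_wavelength_choices`, the
#' senescence analogue). Year effects are shared by all individuals of a
#' population in a calendar year, so mean-centring can remove them;
#' quality is a per-individual intercept shift; noise is observation-level.
#'
#' @param label Population label.
#' @param annual_survival Adult annual survival probability in (0, 1).
#' @param base_clutch Mean clutch size (eggs).
#' @param long_amplitude_mean,short_amplitude_mean Mean peak-to-trough
#'   amplitudes (eggs) of the long- and short-term components.
#' @param p_dominant_long Probability an individual's dominant component is
#'   the long-term one.
#' @param long_wavelength_choices Candidate long wavelengths (years, > 2).
#' @param year_effect_sd,quality_sd,noise_sd Standard deviations (eggs) of
#'   the shared year effect, individual quality, and residual noise.
#' @return A validated `ric_pop_config` list.
#' @export
population_config <- function(label,
                              annual_survival,
                              base_clutch,
                              long_amplitude_mean = 2.5,
                              short_amplitude_mean = 2.0,
                              p_dominant_long = 0.5,
                              long_wavelength_choices = c(4, 6),
                              year_effect_sd = 0.5,
                              quality_sd = 0.5,
                              noise_sd = 0.5) {
  cfg <- list(
    label = as.character(label),
    annual_survival = annual_survival,
    base_clutch = base_clutch,
    long_amplitude_mean = long_amplitude_mean,
    short_amplitude_mean = short_amplitude_mean,
    p_dominant_long = p_dominant_long,
    long_wavelength_choices = long_wavelength_choices,
    year_effect_sd = year_effect_sd,
    quality_sd = quality_sd,
    noise_sd = noise_sd
  )
  if (!(annual_survival > 0 && annual_survival < 1)) {
    stop("annual_survival must lie in (0, 1)", call. = FALSE)
  }
  if (base_clutch <= 0) stop("base_clutch must be positive", call. = FALSE)
  if (long_amplitude_mean < 0 || short_amplitude_mean < 0) {
    stop("amplitude means must be >= 0", call. = FALSE)
  }
  if (p_dominant_long < 0 || p_dominant_long > 1) {
    stop("p_dominant_long must lie in [0, 1]", call. = FALSE)
  }
  if (any(long_wavelength_choices <= 2)) {
    stop("long wavelengths must exceed 2 years", call. = FALSE)
  }
  if (year_effect_sd < 0 || quality_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "ric_pop_config")
}

#' Fast and slow pace-of-life presets
#'
#' Two stylized populations bracketing the deciduous/evergreen blue tit
#' contrast: the fast (deciduous-like) preset has lower annual survival
#' (0.45, within the 0.42-0.47 range reported for deciduous populations),
#' larger clutches, stronger long-term waves and a dominant long-term
#' component in 70% of individuals; the slow (evergreen-like) preset has
#' higher survival (0.56, within 0.55-0.57), smaller clutches and a
#' dominant short-term alternation in 70% of individuals.
#'
#' @param which `"fast"` or `"slow"`.
#' @return A `ric_pop_config`.
#' @export
#' @examples
#' pop_preset("fast")
pop_preset <- function(which = c("fast", "slow")) {
  which <- match.arg(which)
  if (which == "fast") {
    population_config(
      label = "fast", annual_survival = 0.45, base_clutch = 9.5,
      long_amplitude_mean = 3.0, short_amplitude_mean = 1.8,
      p_dominant_long = 0.7
    )
  } else {
    population_config(
      label = "slow", annual_survival = 0.56, base_clutch = 6.5,
      long_amplitude_mean = 1.8, short_amplitude_mean = 2.4,
      p_dominant_long = 0.3
    )
  }
}

#' Maximum simulated age (years); yearly breeders of this kind are not
#' observed breeding beyond age 9.
#' @noRd
.max_age <- 9L

.round_half_up <- function(x) floor(x + 0.5)

#' Simulate one individual's clutch-size series
#'
#' Lifespan is geometric with continuation probability `annual_survival`,
#' capped at 9 breeding years. The clutch in breeding year `t = 0, 1, ...`
#' is `base + quality + u_year(t) + (A_L/2) cos(2 pi t / w_L + phi) +
#' (A_S/2) cos(pi t + psi) + noise`, rounded half-up to an integer egg
#' count (unless `round = FALSE`) and floored at zero. One amplitude is
#' drawn around each component mean; the larger draw is assigned to the
#' individual's dominant component (long-term with probability
#' `p_dominant_long`), so the configured dominance is the ground truth.
#'
#' Deterministic overrides (`lifespan`, `quality`, amplitudes, wavelength,
#' phases, `year_effects`) replace the corresponding random draws; they
#' exist for exact-recovery testing.
#'
#' @param config A `ric_pop_config`.
#' @param round Round clutches to whole eggs (default `TRUE`).
#' @param lifespan,quality,long_amplitude,short_amplitude,long_wavelength
#'   Optional deterministic overrides.
#' @param phase_long,phase_short Optional phases (radians).
#' @param year_effects Optional numeric vector (length >= lifespan) of
#'   shared year effects; defaults to zero.
#' @param dominant Optional `"short"` or `"long"` override.
#' @param id Individual id recorded in the truth row.
#' @return List with `clutch` (numeric vector) and `truth` (one-row
#'   tibble: id, true dominant scale, long wavelength, both true
#'   amplitudes, lifespan, quality).
#' @export
simulate_individual <- function(config, round = TRUE,
                                lifespan = NULL, quality = NULL,
                                long_amplitude = NULL,
                                short_amplitude = NULL,
                                long_wavelength = NULL,
                                phase_long = NULL, phase_short = NULL,
                                year_effects = NULL,
                                dominant = NULL, id = "ind") {
  stopifnot(inherits(config, "ric_pop_config"))
  if (is.null(lifespan)) {
    lifespan <- min(1L + stats::rgeom(1, prob = 1 - config$annual_survival),
                    .max_age)
  }
  L <- as.integer(lifespan)
  stopifnot(L >= 1)
  if (is.null(quality)) quality <- stats::rnorm(1, 0, config$quality_sd)
  if (is.null(dominant)) {
    dominant <- if (stats::runif(1) < config$p_dominant_long) "long"
                else "short"
  }
  if (is.null(long_wavelength)) {
    long_wavelength <-
      config$long_wavelength_choices[
        sample.int(length(config$long_wavelength_choices), 1)]
  }
  draw_amp <- function(m) if (m <= 0) 0 else abs(stats::rnorm(1, m, m / 4))
  if (is.null(long_amplitude) && is.null(short_amplitude)) {
    a_long <- draw_amp(config$long_amplitude_mean)
    a_short <- draw_amp(config$short_amplitude_mean)
    # the dominant component receives the larger of the two draws
    hi <- max(a_long, a_short); lo <- min(a_long, a_short)
    if (dominant == "long") { a_long <- hi; a_short <- lo }
    else { a_short <- hi; a_long <- lo }
  } else {
    a_long <- if (is.null(long_amplitude)) 0 else long_amplitude
    a_short <- if (is.null(short_amplitude)) 0 else short_amplitude
  }
  if (is.null(phase_long)) phase_long <- stats::runif(1, -pi, pi)
  # Nyquist subtlety: sampled yearly, cos(pi t + psi) = cos(psi) (-1)^t, so a
  # free phase would shrink the realized alternation by |cos(psi)| and the
  # drawn short amplitude would not be the ground truth. Restrict the
  # short-term phase to {0, pi} so the injected peak-to-trough is realized.
  if (is.null(phase_short)) phase_short <- sample(c(0, pi), 1)
  if (is.null(year_effects)) year_effects <- rep(0, L)
  stopifnot(length(year_effects) >= L)
  t <- seq_len(L) - 1
  mu <- config$base_clutch + quality + year_effects[seq_len(L)] +
    (a_long / 2) * cos(2 * pi * t / long_wavelength + phase_long) +
    (a_short / 2) * cos(pi * t + phase_short) +
    stats::rnorm(L, 0, config$noise_sd)
  clutch <- if (round) pmax(.round_half_up(mu), 0) else pmax(mu, 0)
  truth <- tibble::tibble(
    individual_id        = id,
    population           = config$label,
    true_dominant_scale  = dominant,
    true_long_wavelength = long_wavelength,
    true_long_amplitude  = a_long,
    true_short_amplitude = a_short,
    lifespan             = L,
    quality              = quality
  )
  list(clutch = clutch, truth = truth)
}

.substream_seed <- function(seed, pop_index, ind_index = 0L) {
  (as.integer(seed) %% 1000003L) * 2011L +
    pop_index * 100003L + ind_index * 613L
}

#' Simulate a multi-population breeding study
#'
#' Draws `n_per_pop` individuals per population configuration, assigns
#' staggered recruitment years across the study window, applies year
#' effects shared within each population-year, and emits a breeding-record
#' table in the ingest schema together with the per-individual ground
#' truth. Individuals with lifespans below three breeding years are
#' included, so downstream filtering is exercised. Each individual draws
#' from its own deterministic substream of `seed`: adding individuals or
#' populations does not perturb earlier ones, and a rerun with the same
#' arguments is identical.
#'
#' @param configs List of `ric_pop_config` (or a single one).
#' @param n_per_pop Individuals per population.
#' @param seed Integer seed governing all randomness.
#' @param start_year First recruitment calendar year.
#' @param n_recruit_years Width of the recruitment window (years).
#' @param round Round clutches to whole eggs.
#' @return List with `records` (breeding-record tibble: one row per
#'   individual-year, `clutch_type = "first"`, `polygamous = FALSE`) and
#'   `truth` (tibble of ground-truth rows with `first_breed_year`).
#' @export
simulate_study <- function(configs, n_per_pop = 100, seed = 1,
                           start_year = 2000, n_recruit_years = 18,
                           round = TRUE) {
  if (inherits(configs, "ric_pop_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, n_per_pop >= 1)
  all_years <- seq(start_year, start_year + n_recruit_years + .max_age - 1L)
  rec_list <- list()
  truth_list <- list()
  for (p in seq_along(configs)) {
    cfg <- configs[[p]]
    # shared year effects for this population, one substream per population
    set.seed(.substream_seed(seed, p, 0L))
    u_year <- stats::setNames(
      stats::rnorm(length(all_years), 0, cfg$year_effect_sd),
      all_years)
    for (i in seq_len(n_per_pop)) {
      set.seed(.substream_seed(seed, p, i))
      first_year <- start_year + sample.int(n_recruit_years, 1) - 1L
      sex <- if (stats::runif(1) < 0.5) "female" else "male"
      yrs_avail <- seq(first_year, max(all_years))
      sim <- simulate_individual(
        cfg, round = round,
        year_effects = unname(u_year[as.character(yrs_avail)]),
        id = sprintf("%s_%03d", cfg$label, i)
      )
      L <- sim$truth$lifespan
      yrs <- yrs_avail[seq_len(L)]
      rec_list[[length(rec_list) + 1L]] <- tibble::tibble(
        individual_id = sim$truth$individual_id,
        population    = cfg$label,
        sex           = sex,
        birth_year    = first_year - 1L,
        breed_year    = yrs,
        age           = seq_len(L),
        clutch_size   = as.integer(.round_half_up(sim$clutch)),
        clutch_real   = sim$clutch,
        clutch_type   = "first",
        polygamous    = FALSE
      )
      truth_list[[length(truth_list) + 1L]] <-
        dplyr::mutate(sim$truth, sex = sex, first_breed_year = first_year)
    }
  }
  records <- dplyr::bind_rows(rec_list)
  list(records = records, truth = dplyr::bind_rows(truth_list))
}
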