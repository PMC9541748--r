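#' Decompose a clutch-size series into reproductive investment curves
#'
#' Demeans the series and computes its discrete Fourier transform at
#' frequency indices `k = 1..floor(n/2)` with one sample per year, so mode
#' `k` is a sine wave of wavelength `n/k` years (wavelengths need not be
#' whole integers). Each mode is a reproductive investment curve (RIC):
#' its peak-to-trough amplitude `A_k = 2 a_k` (twice the mathematical
#' half-amplitude) measures how much investment changes over that temporal
#' scale, and its variance share is the fraction of within-individual
#' variance it carries. For `k < n/2`, `a_k = 2 |c_k| / n`; when `n` is
#' even the Nyquist mode has `a_{n/2} = |c_{n/2}| / n`. The mean plus the
#' sum of all mode sinusoids reconstructs the input exactly, and variance
#' shares sum to one (Parseval) for any non-constant series.
#'
#' Modes are ranked by descending peak-to-trough amplitude; exact ties are
#' resolved toward the longer wavelength so ranking is deterministic. A
#' mode is "present" when its amplitude exceeds `tol`; a constant series
#' has no present modes.
#'
#' @param values Numeric series of length >= 3 (absolute or mean-centred
#'   clutch sizes, ordered by year).
#' @param tol Amplitude below which a mode is treated as absent (eggs).
#' @return A `ric_decomposition`: list with `modes` (tibble: `k`,
#'   `wavelength`, `half_amplitude`, `amplitude` (peak-to-trough), `phase`,
#'   `variance_share`, `present`, `rank`), `n`, `series_mean`, `values`,
#'   `n_present_modes`.
#' @export
#' @examples
#' d <- ric_decompose(c(6, 7, 9, 10, 9, 7))
#' d$modes
ric_decompose <- function(values, tol = 1e-9) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) {
    stop("series too short for Fourier decomposition (need n >= 3, got ",
         n, ")", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  mu <- mean(values)
  y <- values - mu
  cf <- stats::fft(y)
  ks <- seq_len(n %/% 2)
  ck <- cf[ks + 1]
  nyquist <- (n %% 2 == 0) & ks == n / 2
  half_amp <- ifelse(nyquist, Mod(ck) / n, 2 * Mod(ck) / n)
  ss <- sum(y^2)
  contrib <- ifelse(nyquist, Mod(ck)^2 / n, 2 * Mod(ck)^2 / n)
  vshare <- if (ss > 0) contrib / ss else rep(0, length(ks))
  modes <- tibble::tibble(
    k              = ks,
    wavelength     = n / ks,
    half_amplitude = half_amp,
    amplitude      = 2 * half_amp,
    phase          = Arg(ck),
    variance_share = vshare,
    present        = 2 * half_amp > tol
  )
  # rank: amplitude desc, ties to the longer wavelength (smaller k)
  ord <- order(-modes$amplitude, modes$k)
  modes <- modes[ord, , drop = FALSE]
  modes$rank <- seq_len(nrow(modes))
  structure(
    list(
      modes           = modes,
      n               = n,
      series_mean     = mu,
      values          = values,
      n_present_modes = sum(modes$present)
    ),
    class = "ric_decomposition"
  )
}

#' @export
print.ric_decomposition <- function(x, ...) {
  cat(sprintf("RIC decomposition: n = %d, mean = %.3f, %d present mode(s)\n",
              x$n, x$series_mean, x$n_present_modes))
  print(x$modes)
  invisible(x)
}

#' Reconstruct a series from its RIC decomposition
#'
#' @param decomp A `ric_decomposition`.
#' @return Numeric vector: series mean plus the sum of all mode sinusoids,
#'   equal to the original series up to numerical round-off.
#' @export
ric_reconstruct <- function(decomp) {
  n <- decomp$n
  t <- seq_len(n) - 1
  out <- rep(decomp$series_mean, n)
  for (i in seq_len(nrow(decomp$modes))) {
    m <- decomp$modes[i, ]
    out <- out + m$half_amplitude * cos(2 * pi * m$k * t / n + m$phase)
  }
  out
}

#' Dominant and secondary RIC of a decomposition
#'
#' The dominant RIC is the mode with the greatest peak-to-trough amplitude;
#' the secondary RIC the second greatest. Ties go to the longer wavelength.
#'
#' @param decomp A `ric_decomposition`.
#' @return List with `dominant` and `secondary`, each a one-row mode tibble
#'   or `NULL` when absent (no present modes / fewer than two).
#' @export
ric_dominant <- function(decomp) {
  pres <- decomp$modes[decomp$modes$present, , drop = FALSE]
  list(
    dominant  = if (nrow(pres) >= 1) pres[1, ] else NULL,
    secondary = if (nrow(pres) >= 2) pres[2, ] else NULL
  )
}

#' Classify the temporal scale of an individual's RICs
#'
#' Groups the dominant (and, when present, secondary) RIC into short-term
#' versus long-term. The default rule follows the observed wavelength
#' distribution of yearly breeders: short-term means a wavelength of
#' exactly 2 years (the Nyquist alternation, within `1e-9`), long-term
#' anything greater. The alternative `"below_4"` rule classifies any
#' wavelength under 4 years as short-term, a robustness variant.
#'
#' @param decomp A `ric_decomposition`.
#' @param short_cutoff Wavelength (years) at or below which a mode is
#'   short-term under the default rule.
#' @param cutoff_mode `"inclusive_at_2"` (wavelength <= `short_cutoff`) or
#'   `"below_4"` (wavelength < 4).
#' @return One-row tibble: dominant/secondary wavelength, amplitude and
#'   scale, plus `has_short_and_long`.
#' @export
ric_classify <- function(decomp, short_cutoff = 2,
                         cutoff_mode = c("inclusive_at_2", "below_4")) {
  cutoff_mode <- match.arg(cutoff_mode)
  ds <- ric_dominant(decomp)
  if (is.null(ds$dominant)) {
    stop("cannot classify a series with no present Fourier modes",
         call. = FALSE)
  }
  scale_of <- function(w) {
    short <- switch(cutoff_mode,
      inclusive_at_2 = w <= short_cutoff + 1e-9,
      below_4        = w < 4
    )
    if (short) "short" else "long"
  }
  dom <- ds$dominant
  sec <- ds$secondary
  tibble::tibble(
    dominant_wavelength  = dom$wavelength,
    dominant_amplitude   = dom$amplitude,
    dominant_scale       = scale_of(dom$wavelength),
    secondary_wavelength = if (is.null(sec)) NA_real_ else sec$wavelength,
    secondary_amplitude  = if (is.null(sec)) NA_real_ else sec$amplitude,
    secondary_scale      = if (is.null(sec)) NA_character_
                           else scale_of(sec$wavelength),
    has_short_and_long   = !is.null(sec) &&
      scale_of(dom$wavelength) != scale_of(sec$wavelength)
  )
}

#' Decompose and classify every individual in a series table
#'
#' Runs [ric_decompose()] and [ric_classify()] on each retained individual,
#' for the absolute or mean-centred clutch measure. Individuals whose
#' series is constant under the chosen measure carry no oscillatory signal
#' and are omitted (their count is attached as attribute `n_no_modes`);
#' this is why sample sizes can differ slightly between the two measures.
#'
#' @param series Nested series tibble from [prepare_series()].
#' @param measure `"absolute"` or `"centred"`.
#' @inheritParams ric_classify
#' @param tol Present-mode amplitude tolerance passed to [ric_decompose()].
#' @return Tibble, one row per classifiable individual: id, population,
#'   sex, birth year, series length, mean individual clutch,
#'   `n_present_modes`, and the [ric_classify()] columns. Attribute
#'   `n_no_modes` counts omitted constant series.
#' @export
ric_classify_cohort <- function(series, measure = c("absolute", "centred"),
                                short_cutoff = 2,
                                cutoff_mode = c("inclusive_at_2", "below_4"),
                                tol = 1e-9) {
  measure <- match.arg(measure)
  cutoff_mode <- match.arg(cutoff_mode)
  vals <- if (measure == "absolute") series$clutch else series$centred
  if (measure == "centred" && any(vapply(vals, is.null, logical(1)))) {
    stop("centred values not populated; run centre_series() first",
         call. = FALSE)
  }
  rows <- vector("list", nrow(series))
  n_no_modes <- 0L
  for (i in seq_len(nrow(series))) {
    dec <- ric_decompose(vals[[i]], tol = tol)
    if (dec$n_present_modes == 0) {
      n_no_modes <- n_no_modes + 1L
      next
    }
    cls <- ric_classify(dec, short_cutoff = short_cutoff,
                        cutoff_mode = cutoff_mode)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        individual_id          = series$individual_id[i],
        population             = series$population[i],
        sex                    = series$sex[i],
        birth_year             = series$birth_year[i],
        n                      = series$n[i],
        mean_individual_clutch = series$mean_individual_clutch[i],
        measure                = measure,
        n_present_modes        = dec$n_present_modes
      ),
      cls
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_no_modes") <- n_no_modes
  out
}

#' Full mode table for a cohort
#'
#' All candidate Fourier modes of every individual, long format, for export
#' or wavelength-distribution summaries.
#'
#' @inheritParams ric_classify_cohort
#' @return Tibble: individual_id, measure, k, wavelength, peak-to-trough
#'   amplitude, phase, variance share, rank, present flag.
#' @export
ric_mode_table <- function(series, measure = c("absolute", "centred"),
                           tol = 1e-9) {
  measure <- match.arg(measure)
  vals <- if (measure == "absolute") series$clutch else series$centred
  purrr::map2_dfr(series$individual_id, vals, function(id, v) {
    m <- ric_decompose(v, tol = tol)$modes
    dplyr::bind_cols(
      tibble::tibble(individual_id = id, measure = measure)[
        rep(1, nrow(m)), ], m)
  })
}

#' Cohort-level summary of RIC classifications
#'
#' @param classifications Output of [ric_classify_cohort()].
#' @return List with: `n`, `prop_dominant_short` overall,
#'   `prop_dominant_short_by_population` (tibble), the distribution of
#'   dominant wavelengths (tibble `wavelength`, `n`, `prop`),
#'   `prop_multi_mode` (share with >= 2 present modes), and
#'   `prop_short_and_long` (share whose two leading modes span both
#'   scales, among individuals with a secondary mode).
#' @export
ric_cohort_summary <- function(classifications) {
  stopifnot(nrow(classifications) > 0)
  cl <- classifications
  by_pop <- cl |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_dominant_short = mean(.data$dominant_scale == "short"),
      prop_dominant_long  = mean(.data$dominant_scale == "long"),
      .groups = "drop"
    )
  wl <- cl |>
    dplyr::count(wavelength = round(.data$dominant_wavelength, 6)) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$prop))
  has_sec <- !is.na(cl$secondary_wavelength)
  list(
    n                        = nrow(cl),
    prop_dominant_short      = mean(cl$dominant_scale == "short"),
    prop_dominant_long       = mean(cl$dominant_scale == "long"),
    prop_dominant_short_by_population = by_pop,
    dominant_wavelengths     = wl,
    prop_multi_mode          = mean(cl$n_present_modes >= 2),
    prop_short_and_long      = if (any(has_sec))
      mean(cl$has_short_and_long[has_sec]) else NA_real_
  )
}

#' Compare a single-mode RIC fit with quadratic and lag-1 fits
#'
#' Benchmarks the best single Fourier mode against the two conventional
#' descriptions of reproductive-investment change: a quadratic age model
#' (senescence-style smooth trend) and a state-dependent model regressing
#' each value on the previous year's value (one-year carry-over).
#'
#' @param values Numeric clutch series, length >= 4.
#' @param age Integer ages aligned with `values`.
#' @return Named numeric: `r2_fourier` (variance share of the best single
#'   mode), `r2_quadratic` and `r2_lag1` (ordinary least-squares R^2),
#'   all in \code{[0, 1]}.
#' @export
#' @examples
#' ric_compare_fits(c(6, 7, 9, 10, 9, 7), 1:6)
ric_compare_fits <- function(values, age) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) {
    stop("need n >= 4 to fit the quadratic comparison model", call. = FALSE)
  }
  stopifnot(length(age) == n)
  dec <- ric_decompose(values)
  r2_fourier <- max(dec$modes$variance_share)
  d <- data.frame(y = values, age = as.numeric(age))
  # exact fits are legitimate inputs here; silence the perfect-fit warning
  r2_quadratic <- suppressWarnings(
    summary(stats::lm(y ~ age + I(age^2), data = d))$r.squared)
  dl <- data.frame(y = values[-1], ylag = values[-n])
  r2_lag1 <- suppressWarnings(
    summary(stats::lm(y ~ ylag, data = dl))$r.squared)
  c(r2_fourier = r2_fourier, r2_quadratic = r2_quadratic, r2_lag1 = r2_lag1)
}
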