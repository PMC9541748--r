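# Brute-force direct-summation DFT, independent of the package's fft path.
# Returns one row per candidate frequency index with the same amplitude
# conventions the package documents.
brute_dft <- function(values) {
  n <- length(values)
  y <- values - mean(values)
  t <- seq_len(n) - 1
  ks <- seq_len(n %/% 2)
  out <- lapply(ks, function(k) {
    ck <- sum(y * exp(-2i * pi * k * t / n))
    half <- if (n %% 2 == 0 && k == n / 2) Mod(ck) / n else 2 * Mod(ck) / n
    data.frame(k = k, wavelength = n / k, amplitude = 2 * half,
               phase = Arg(ck))
  })
  do.call(rbind, out)
}

# Minimal valid breeding-record tibble; override any field via ...
toy_records <- function(n = 1, ...) {
  base <- tibble::tibble(
    individual_id = paste0("b", seq_len(n)),
    population    = "A",
    sex           = "female",
    birth_year    = 2000L,
    breed_year    = 2001L,
    age           = 1L,
    clutch_size   = 8L,
    clutch_type   = "first",
    polygamous    = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# One individual breeding in consecutive (or given) years.
toy_series_records <- function(id, years, clutch, population = "A",
                               sex = "female", birth_year = NULL) {
  if (is.null(birth_year)) birth_year <- min(years) - 1L
  tibble::tibble(
    individual_id = id,
    population    = population,
    sex           = sex,
    birth_year    = as.integer(birth_year),
    breed_year    = as.integer(years),
    age           = as.integer(years - birth_year),
    clutch_size   = as.integer(clutch),
    clutch_type   = "first",
    polygamous    = FALSE
  )
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE)
  path
}
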