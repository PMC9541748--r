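#' Build the individual-level analysis table
#'
#' One row per classified individual, carrying the binary dominant
#' time-scale response (0 = short-term, 1 = long-term) and the
#' peak-to-trough amplitudes of the short- and long-term RIC among the two
#' leading modes (absent when the individual shows no mode of that scale).
#' Population, sex and birth year become factors; reference levels default
#' to the first level present, or the given ones when supplied (for the
#' blue tit study tables these are population D-Muro and sex female).
#'
#' @param classifications Output of [ric_classify_cohort()].
#' @param ref_population,ref_sex Optional reference factor levels.
#' @return Tibble with columns `individual_id`, `population`, `sex`,
#'   `birth_year` (factor), `mean_individual_clutch`,
#'   `dominant_scale_binary`, `amplitude_short`, `amplitude_long`,
#'   `measure`.
#' @export
analysis_table <- function(classifications, ref_population = NULL,
                           ref_sex = NULL) {
  cl <- classifications
  amp_of <- function(scale) {
    ifelse(cl$dominant_scale == scale, cl$dominant_amplitude,
           ifelse(!is.na(cl$secondary_scale) & cl$secondary_scale == scale,
                  cl$secondary_amplitude, NA_real_))
  }
  out <- tibble::tibble(
    individual_id          = cl$individual_id,
    population             = factor(cl$population),
    sex                    = factor(cl$sex),
    birth_year             = factor(cl$birth_year),
    mean_individual_clutch = cl$mean_individual_clutch,
    dominant_scale_binary  = as.integer(cl$dominant_scale == "long"),
    amplitude_short        = amp_of("short"),
    amplitude_long         = amp_of("long"),
    measure                = cl$measure
  )
  if (!is.null(ref_population)) {
    out$population <- stats::relevel(out$population, ref = ref_population)
  }
  if (!is.null(ref_sex)) {
    out$sex <- stats::relevel(out$sex, ref = ref_sex)
  }
  out
}

#' Drop rows with non-positive response before a log transform
#'
#' @param data Analysis tibble.
#' @param response Response column name.
#' @return List with `data` (rows with `response > 0`) and `n_dropped`.
#' @export
drop_zero_amplitudes <- function(data, response) {
  keep <- !is.na(data[[response]]) & data[[response]] > 0
  list(data = data[keep, , drop = FALSE],
       n_dropped = sum(!is.na(data[[response]]) & data[[response]] <= 0))
}

#' Enumerate the all-subsets candidate model set
#'
#' Every subset of the fixed-effect pool, intercept-only included; all
#' candidates carry the birth-year random intercept.
#'
#' @param fixed_pool Character vector of fixed-effect term names.
#' @return Tibble with `model_id`, `label` and a `terms` list-column,
#'   ordered from the intercept-only model to the full model.
#' @export
#' @examples
#' enumerate_candidates()
enumerate_candidates <- function(fixed_pool = c("mean_individual_clutch",
                                                "population", "sex")) {
  p <- length(fixed_pool)
  subsets <- list(character(0))
  if (p > 0) {
    idx <- unlist(lapply(seq_len(p), function(m)
      utils::combn(p, m, simplify = FALSE)), recursive = FALSE)
    subsets <- c(subsets, lapply(idx, function(i) fixed_pool[i]))
  }
  tibble::tibble(
    model_id = seq_along(subsets),
    label = vapply(subsets, function(s)
      if (length(s) == 0) "1" else paste(s, collapse = " + "), character(1)),
    terms = subsets
  )
}

#' Fit one candidate model
#'
#' Binary responses use a logistic mixed model (`lme4::glmer`, logit link);
#' amplitude responses use a Gaussian mixed model on the transformed scale
#' (`lme4::lmer`, maximum likelihood, not REML, so AICc is comparable
#' across fixed-effect structures). The transform is written into the model
#' formula (`log(y)` / `sqrt(y)`) so downstream marginal means can be
#' back-transformed automatically.
#'
#' @param data Analysis tibble (see [analysis_table()]).
#' @param response Response column name.
#' @param terms Character vector of fixed-effect terms (may be empty).
#' @param family `"binomial"` or `"gaussian"`.
#' @param transform `"none"`, `"log"` or `"sqrt"` (Gaussian only).
#' @return List of class `ric_fit`: `fit` (merMod), `terms`, `label`,
#'   `family`, `transform`, `response`, `converged`, `messages`.
#' @export
fit_candidate <- function(data, response, terms = character(0),
                          family = c("binomial", "gaussian"),
                          transform = c("none", "log", "sqrt")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (family == "binomial" && transform != "none") {
    stop("binary responses are fitted on the logit scale without a ",
         "response transform", call. = FALSE)
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (nrow(data) == 0) stop("no data to fit", call. = FALSE)
  if (transform == "log" && any(data[[response]] <= 0)) {
    stop("log transform with non-positive amplitudes; drop zero-amplitude ",
         "rows first (see drop_zero_amplitudes())", call. = FALSE)
  }
  lhs <- switch(transform,
    none = response,
    log  = sprintf("log(%s)", response),
    sqrt = sprintf("sqrt(%s)", response)
  )
  rhs <- paste(c("1", terms, "(1 | birth_year)"), collapse = " + ")
  fml <- stats::as.formula(paste(lhs, "~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (family == "binomial") {
      # bobyqa avoids spurious gradient-check failures on small cohorts
      lme4::glmer(fml, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    } else {
      lme4::lmer(fml, data = data, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa"))
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      # singular (zero-variance) fits are legitimate boundary estimates
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv_bad <- any(grepl("failed to converge", msgs, fixed = TRUE))
  structure(
    list(fit = fit, terms = terms,
         label = if (length(terms) == 0) "1"
                 else paste(terms, collapse = " + "),
         family = family, transform = transform, response = response,
         converged = !conv_bad, messages = msgs),
    class = "ric_fit"
  )
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`, where `k` counts
#' estimated parameters: fixed effects plus the random-intercept variance
#' (plus the residual variance for Gaussian models), i.e. the df of the
#' maximized log-likelihood.
#'
#' @param loglik Maximized log-likelihood, or a `ric_fit` / `merMod` object
#'   from which `loglik`, `k` and `n` are extracted.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-567.47, k = 4, n = 633)
aicc <- function(loglik, k = NULL, n = NULL) {
  if (inherits(loglik, "ric_fit")) loglik <- loglik$fit
  if (inherits(loglik, "merMod")) {
    ll <- stats::logLik(loglik)
    k <- attr(ll, "df")
    n <- stats::nobs(loglik)
    loglik <- as.numeric(ll)
  }
  stopifnot(is.numeric(loglik), is.numeric(k), is.numeric(n))
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Delta-AICc and Akaike weights
#'
#' @param aicc_values Numeric vector of AICc values over a candidate set.
#' @return List with `delta` (differences from the minimum) and `weight`
#'   (`exp(-delta/2)` normalized to sum to one).
#' @export
#' @examples
#' akaike_weights(c(1082.5, 1083.1, 1083.4))
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) > 0)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Fit and rank the all-subsets candidate set for one response
#'
#' Fits every candidate (see [enumerate_candidates()]), computes AICc,
#' delta-AICc and Akaike weights, and flags the retained set (delta below
#' `retain_threshold`, default 2). Non-converged fits are excluded from the
#' ranking with a warning.
#'
#' @inheritParams fit_candidate
#' @param fixed_pool Fixed-effect pool for [enumerate_candidates()].
#' @param retain_threshold Delta-AICc cut for the retained set.
#' @return List of class `ric_selection`: `table` (tibble: label, df,
#'   logLik, AICc, delta, weight, retained, converged), `fits` (list of
#'   `ric_fit` in table order), `response`, `family`, `transform`,
#'   `n_obs`, `n_dropped_zero`, `retain_threshold`.
#' @export
model_selection <- function(data, response,
                            family = c("binomial", "gaussian"),
                            transform = c("none", "log", "sqrt"),
                            fixed_pool = c("mean_individual_clutch",
                                           "population", "sex"),
                            retain_threshold = 2) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  n_dropped <- 0L
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (transform == "log") {
    dz <- drop_zero_amplitudes(data, response)
    data <- dz$data
    n_dropped <- dz$n_dropped
  }
  data <- droplevels(data)
  cand <- enumerate_candidates(fixed_pool)
  fits <- lapply(cand$terms, function(tr)
    fit_candidate(data, response, terms = tr, family = family,
                  transform = transform))
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " candidate model(s) failed to converge and were ",
            "excluded from selection: ",
            paste(cand$label[!ok], collapse = "; "), call. = FALSE)
  }
  fits <- fits[ok]
  cand <- cand[ok, , drop = FALSE]
  lls <- lapply(fits, function(f) stats::logLik(f$fit))
  tab <- tibble::tibble(
    label  = cand$label,
    terms  = cand$terms,
    df     = vapply(lls, function(l) as.integer(attr(l, "df")), integer(1)),
    logLik = vapply(lls, as.numeric, numeric(1)),
    AICc   = vapply(fits, aicc, numeric(1))
  )
  aw <- akaike_weights(tab$AICc)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  tab$retained <- tab$delta < retain_threshold
  ord <- order(tab$AICc)
  structure(
    list(table = tab[ord, , drop = FALSE], fits = fits[ord],
         response = response, family = family, transform = transform,
         n_obs = nrow(data), n_dropped_zero = n_dropped,
         retain_threshold = retain_threshold),
    class = "ric_selection"
  )
}

#' @export
print.ric_selection <- function(x, ...) {
  cat(sprintf("Model selection for %s (%s%s), n = %d\n", x$response,
              x$family,
              if (x$transform != "none") paste0(", ", x$transform) else "",
              x$n_obs))
  if (x$n_dropped_zero > 0) {
    cat(sprintf("  %d zero-amplitude row(s) dropped before log transform\n",
                x$n_dropped_zero))
  }
  print(dplyr::select(x$table, -"terms"))
  invisible(x)
}

#' Which models fall within the delta-AICc retention window
#'
#' Applies the retained-set rule to a delta-AICc column alone: keep every
#' model with delta strictly below the threshold (the best model, delta 0,
#' is always kept).
#'
#' @param delta Numeric vector of delta-AICc values.
#' @param threshold Retention cut (default 2).
#' @return Logical vector.
#' @export
#' @examples
#' retained_set(c(0, 0.52, 0.9, 0.98, 1.78, 2.26, 2.68, 2.76))
retained_set <- function(delta, threshold = 2) {
  stopifnot(all(delta >= -1e-9))
  delta < threshold
}

#' Weighted model averaging over the retained set
#'
#' Renormalizes Akaike weights over the retained models and averages each
#' fixed-effect coefficient. `"conditional"` averaging (default) averages a
#' term only over the retained models that contain it, with weights
#' renormalized within that subset; `"full"` averaging treats the
#' coefficient as zero in models that omit the term.
#'
#' @param selection A `ric_selection`.
#' @param method `"conditional"` or `"full"`.
#' @return Tibble with `term`, `estimate`, `n_models` (retained models
#'   containing the term) and `method`; attribute `retained_labels` lists
#'   the averaged models.
#' @export
average_models <- function(selection, method = c("conditional", "full")) {
  method <- match.arg(method)
  tab <- selection$table
  keep <- tab$retained
  fits <- selection$fits[keep]
  w <- tab$weight[keep]
  w <- w / sum(w)
  coefs <- lapply(fits, function(f) lme4::fixef(f$fit))
  terms <- unique(unlist(lapply(coefs, names)))
  est <- vapply(terms, function(tm) {
    present <- vapply(coefs, function(cf) tm %in% names(cf), logical(1))
    b <- vapply(coefs[present], function(cf) cf[[tm]], numeric(1))
    if (method == "conditional") {
      sum(b * w[present] / sum(w[present]))
    } else {
      sum(b * w[present])  # omitted models contribute 0
    }
  }, numeric(1))
  n_models <- vapply(terms, function(tm)
    sum(vapply(coefs, function(cf) tm %in% names(cf), logical(1))),
    numeric(1))
  out <- tibble::tibble(term = terms, estimate = unname(est),
                        n_models = as.integer(n_models), method = method)
  attr(out, "retained_labels") <- tab$label[keep]
  out
}

#' Estimated marginal means on the response scale
#'
#' Marginal means for one factor from a fitted candidate model: other
#' factors are averaged with equal level weights, continuous covariates
#' held at their grand mean, random effects at zero, and predictions
#' back-transformed to the response scale (inverse logit for the binary
#' time-scale models; the log / square-root transforms are read from the
#' model formula) with delta-method standard errors. When the factor is
#' absent from the model the overall marginal mean is returned with a note.
#'
#' @param fit A `ric_fit` (typically the best model of a `ric_selection`).
#' @param factor_name Factor to compute means for, e.g. `"population"`.
#' @return Tibble: `level`, `estimate` (response scale), `se`, `note`.
#' @export
ric_marginal_means <- function(fit, factor_name = "population") {
  stopifnot(inherits(fit, "ric_fit"))
  in_model <- factor_name %in% fit$terms
  spec <- if (in_model) stats::as.formula(paste("~", factor_name))
          else ~1
  emm <- emmeans::emmeans(fit$fit, specs = spec, type = "response")
  s <- as.data.frame(summary(emm))
  est_col <- intersect(c("prob", "response", "emmean"), names(s))[1]
  tibble::tibble(
    level    = if (in_model) as.character(s[[factor_name]]) else "overall",
    estimate = s[[est_col]],
    se       = s[["SE"]],
    note     = if (in_model) "" else
      paste0("'", factor_name, "' not in model; grand mean returned")
  )
}

#' Best model of a selection
#'
#' @param selection A `ric_selection`.
#' @return The `ric_fit` with the minimum AICc.
#' @export
best_model <- function(selection) {
  selection$fits[[1]]
}
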