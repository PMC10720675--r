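#' Specification for a synthetic patient cohort
#'
#' Describes a cohort whose survival times depend on a single dichotomized
#' lymph-node feature with a planted hazard ratio. Times are exponential
#' (constant baseline hazard, so proportional hazards hold exactly) with
#' independent exponential censoring; per-patient LN features are sampled
#' from clinically plausible distributions centred near the published
#' cut-offs so both groups are populated.
#'
#' @param n_patients number of patients (>= 2).
#' @param lns_per_patient integer range of assessed LNs per patient.
#' @param feature_effect list with `feature` (one of the aggregate columns,
#'   e.g. `"mean_gc_count"`), `cutoff`, `hr` (> 0; hazard multiplier for the
#'   above-cut-off group) and `orientation` (`"gte"` or `"gt"`).
#' @param baseline_hazard events per month in the reference group.
#' @param censoring_rate independent exponential censoring rate (>= 0; 0
#'   means no censoring at all unless `admin_censor` is finite).
#' @param admin_censor optional administrative censoring time in months
#'   (default `Inf`, none).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 400L,
                        lns_per_patient = c(1L, 10L),
                        feature_effect = list(feature = "mean_gc_count",
                                              cutoff = 2, hr = 0.3,
                                              orientation = "gte"),
                        baseline_hazard = 0.02,
                        censoring_rate = 0.005,
                        admin_censor = Inf,
                        seed = 1L) {
  stopifnot(is.list(feature_effect),
            all(c("feature", "cutoff", "hr") %in% names(feature_effect)))
  feature_effect$orientation <- feature_effect$orientation %||% "gte"
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (feature_effect$hr <= 0) stop("hazard ratio must be > 0")
  assert_scalar_num(baseline_hazard, "baseline_hazard", lo = 1e-9)
  assert_scalar_num(censoring_rate, "censoring_rate", lo = 0)
  structure(list(n_patients = as.integer(n_patients),
                 lns_per_patient = as_range(lns_per_patient, "lns_per_patient"),
                 feature_effect = feature_effect,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 admin_censor = admin_censor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with LN features and survival outcomes
#'
#' Per patient, LN-level features are sampled (GC count from a
#' gamma-Poisson mixture with mean 2; mean GC area log-normal around
#' 0.05 mm^2; circularity scaled-beta in `[0.3, 0.95]`; normalized sinus
#' area beta with median near 0.13; SCS width log-normal around 20 um),
#' aggregated to patient level, dichotomized at the planted cut-off, and
#' survival is drawn as `Exp(baseline * hr^I(high))` with independent
#' exponential plus administrative censoring.
#'
#' @param cspec a [cohort_spec()].
#' @return tibble with one row per LN: `patient_id`, `ln_id`, `involvement`,
#'   LN feature columns, patient covariates (`age`, `grade`), `time` (months),
#'   `event` (0/1) and the planted group indicator `high_risk_feature`.
#'   Patient-level rows can be recovered with [aggregate_patient()].
#' @export
generate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  withr::with_seed(cspec$seed, generate_cohort_impl(cspec))
}

generate_cohort_impl <- function(cspec) {
  fe <- cspec$feature_effect
  n <- cspec$n_patients
  n_ln <- sample_int_range(n, cspec$lns_per_patient)
  ln_positive <- rbinom(n, 1, 0.6)
  age <- round(rnorm(n, 55, 11))
  grade <- sample.int(3L, n, replace = TRUE, prob = c(0.15, 0.35, 0.5))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_ln[i]
    lam <- rgamma(1, shape = 2, scale = 1)        # patient GC propensity, mean 2
    gc_count <- rpois(k, lam)
    mean_gc_area <- ifelse(gc_count > 0,
                           exp(rnorm(k, log(0.05), 0.45)), NA_real_)
    mean_gc_circ <- ifelse(gc_count > 0,
                           0.3 + 0.65 * rbeta(k, 5, 2), NA_real_)
    norm_sinus <- rbeta(k, 2.2, 12.5)             # median near 0.13
    scs_width <- exp(rnorm(k, log(20), 0.45))
    involved <- if (ln_positive[i] == 1) rbinom(k, 1, 0.45) else rep(0L, k)
    if (ln_positive[i] == 1 && !any(involved == 1)) involved[1] <- 1L
    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%04d", i),
      ln_id = sprintf("P%04d-LN%02d", i, seq_len(k)),
      involvement = ifelse(involved == 1, "involved", "cancer_free"),
      gc_count = gc_count,
      mean_gc_area_mm2 = mean_gc_area,
      mean_gc_circularity = mean_gc_circ,
      normalized_sinus_area = norm_sinus,
      sinus_area_mm2 = norm_sinus * exp(rnorm(k, log(18), 0.3)) / 10,
      scs_width_um = scs_width,
      age = age[i], grade = grade[i],
      n_involved_lns = sum(involved))
  }
  ln_tbl <- dplyr::bind_rows(rows)

  agg <- aggregate_patient(ln_tbl, mode = "mean", subset = "all")
  feat <- agg[[fe$feature]]
  if (is.null(feat)) stop(sprintf("unknown planted feature `%s`", fe$feature))
  high <- if (identical(fe$orientation, "gt")) feat > fe$cutoff else feat >= fe$cutoff
  high[is.na(high)] <- FALSE
  if (length(unique(high)) < 2L)
    warning("degenerate cohort spec: all patients fall in one feature group")

  hazard <- cspec$baseline_hazard * fe$hr ^ as.numeric(high)
  t_event <- rexp(n, rate = hazard)
  t_cens <- if (cspec$censoring_rate > 0) rexp(n, rate = cspec$censoring_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, cspec$admin_censor)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  pat <- tibble::tibble(patient_id = agg$patient_id,
                        high_risk_feature = as.integer(high),
                        time = time, event = event)
  dplyr::left_join(ln_tbl, pat, by = "patient_id")
}
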