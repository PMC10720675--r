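#' Aggregate LN-level features to patient level
#'
#' Averaging across assessed LNs is the default; `total_gc` (sum of GC
#' counts) and `max_sinus` (LN with the maximum sinus area) support cohorts
#' with few LNs per patient. The LN subset can be restricted by involvement
#' label; patients with no LN in the subset are excluded (reported missing).
#'
#' @param ln_tbl tibble with one row per LN: `patient_id`, `involvement`,
#'   and feature columns (`gc_count`, `mean_gc_area_mm2`,
#'   `mean_gc_circularity`, `sinus_area_mm2`, `normalized_sinus_area`,
#'   `scs_width_um` as available). Extra patient-constant columns (e.g.
#'   `age`, `grade`, `time`, `event`) are carried through.
#' @param mode `"mean"`, `"total_gc"` or `"max_sinus"`.
#' @param subset `"all"`, `"involved"` or `"cancer_free"`.
#' @return tibble with one row per patient; aggregate columns are named
#'   `mean_gc_count`, `mean_gc_area_mm2`, ... for mode `"mean"`, plus
#'   `total_gc_count` / `max_sinus_area_mm2` for the other modes.
#' @export
aggregate_patient <- function(ln_tbl, mode = c("mean", "total_gc", "max_sinus"),
                              subset = c("all", "involved", "cancer_free")) {
  mode <- match.arg(mode)
  subset <- match.arg(subset)
  stopifnot("patient_id" %in% names(ln_tbl))
  sub <- if (subset == "all") ln_tbl else ln_tbl[ln_tbl$involvement == subset, ]
  feat_cols <- intersect(c("gc_count", "mean_gc_area_mm2", "mean_gc_circularity",
                           "sinus_area_mm2", "normalized_sinus_area",
                           "scs_width_um"), names(ln_tbl))
  carry <- setdiff(names(ln_tbl), c(feat_cols, "ln_id", "section_id", "involvement"))
  carried <- dplyr::summarise(dplyr::group_by(ln_tbl[, carry], .data$patient_id),
                              dplyr::across(dplyr::everything(), dplyr::first),
                              .groups = "drop")
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  ag <- dplyr::group_by(sub, .data$patient_id)
  out <- switch(mode,
    mean = dplyr::summarise(ag,
      mean_gc_count = mean_na(.data$gc_count),
      dplyr::across(dplyr::any_of(setdiff(feat_cols, "gc_count")), mean_na),
      n_lns = dplyr::n(), .groups = "drop"),
    total_gc = dplyr::summarise(ag,
      total_gc_count = sum(.data$gc_count, na.rm = TRUE),
      n_lns = dplyr::n(), .groups = "drop"),
    max_sinus = dplyr::summarise(ag,
      max_sinus_area_mm2 = max(.data$sinus_area_mm2, na.rm = TRUE),
      max_normalized_sinus_area = if ("normalized_sinus_area" %in% feat_cols)
        max(.data$normalized_sinus_area, na.rm = TRUE) else NA_real_,
      n_lns = dplyr::n(), .groups = "drop"))
  dplyr::left_join(carried, out, by = "patient_id")
}

#' Dichotomize a feature at a cut-off
#'
#' Boundary conventions follow the printed analyses: `"gte"` labels
#' `value >= cutoff` as `"high"` (e.g. "<2 versus >=2" GCs, ">=20 um" SCS),
#' `"gt"` labels `value > cutoff` as `"high"` (e.g. "<=0.13 versus >0.13").
#'
#' @param values numeric vector (NA allowed, propagated).
#' @param cutoff finite cut-off.
#' @param orientation `"gte"` or `"gt"`.
#' @return factor with levels `c("low", "high")`; attribute `degenerate` is
#'   `TRUE` (with a warning) when all non-missing values fall on one side.
#' @export
dichotomize <- function(values, cutoff, orientation = c("gte", "gt")) {
  orientation <- match.arg(orientation)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  high <- if (orientation == "gte") values >= cutoff else values > cutoff
  g <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  tab <- table(g)
  degen <- any(tab == 0)
  if (degen) warning("dichotomize: all values fall on one side of the cut-off")
  structure(g, degenerate = degen)
}

#' Named cut-off presets for TNBC lymph-node features
#'
#' The `tnbc` preset encodes the published prognostic cut-offs with their
#' boundary conventions: mean GC count 2 (>=), mean GC area 0.015 mm^2 (>),
#' mean GC circularity 0.69 (>), normalized sinus area 0.13 (>), SCS width
#' 20 um (>=). Because the normalized sinus cut-off is printed with an area
#' unit while the normalization itself is dimensionless, the preset carries
#' the same 0.13 cut for both the dimensionless ratio and the absolute
#' sinus area so either reading can be analysed.
#'
#' @param preset preset name (currently `"tnbc"`).
#' @return tibble with `feature`, `cutoff`, `orientation`.
#' @export
cutoff_preset <- function(preset = "tnbc") {
  if (!identical(preset, "tnbc")) stop(sprintf("unknown preset `%s`", preset))
  tibble::tibble(
    feature = c("mean_gc_count", "mean_gc_area_mm2", "mean_gc_circularity",
                "normalized_sinus_area", "sinus_area_mm2", "scs_width_um"),
    cutoff = c(2, 0.015, 0.69, 0.13, 0.13, 20),
    orientation = c("gte", "gt", "gt", "gt", "gt", "gte"))
}

#' Minimal-p cut-point optimization
#'
#' Scans every observed unique value whose induced split keeps both groups
#' at or above `min_group_frac` of the sample and returns the cut
#' minimizing the log-rank p value. By construction the returned p is not
#' adjusted for the multiplicity of candidate cuts and is optimistically
#' biased; treat it as a ranking device, not an inference.
#'
#' @param values numeric feature vector.
#' @param time,event survival outcome.
#' @param min_group_frac minimum group fraction in `(0, 0.5)`.
#' @param orientation boundary convention passed to [dichotomize()].
#' @return list: `cutoff`, `p` (minimal log-rank p), `n_cuts` examined,
#'   `scan` tibble of all admissible cuts.
#' @export
optimal_cutoff <- function(values, time, event, min_group_frac = 0.1,
                           orientation = "gte") {
  if (min_group_frac <= 0 || min_group_frac >= 0.5)
    stop("min_group_frac must be in (0, 0.5)")
  ok <- is.finite(values) & is.finite(time)
  values <- values[ok]; time <- time[ok]; event <- event[ok]
  cand <- sort(unique(values))
  if (length(cand) < 2L) stop("need at least 2 distinct values to scan cuts")
  n <- length(values)
  rows <- list()
  for (cv in cand) {
    g <- if (orientation == "gte") values >= cv else values > cv
    n1 <- sum(g)
    if (n1 < min_group_frac * n || (n - n1) < min_group_frac * n) next
    p <- tryCatch(logrank_p(time, event, g), error = function(e) NA_real_)
    if (is.na(p)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(cutoff = cv, n_high = n1, p = p)
  }
  if (!length(rows)) stop("no admissible cut keeps both groups large enough")
  scan <- dplyr::bind_rows(rows)
  best <- scan[which.min(scan$p), ]
  list(cutoff = best$cutoff, p = best$p, n_cuts = nrow(scan), scan = scan)
}

logrank_p <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit estimates per group plus the log-rank test. `p_method
#' = "permutation"` replaces the asymptotic chi-square p by the exact
#' conditional permutation distribution of the log-rank statistic
#' (exhaustive when the number of group assignments is small, Monte Carlo
#' otherwise), which is preferable at very small n.
#'
#' @param time,event survival outcome (event 0/1, >= 1 event overall).
#' @param group two-level factor / logical.
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration
#'   exceeds `max_exhaustive`.
#' @param max_exhaustive largest number of assignments enumerated exactly.
#' @return object of class `nm_km`: list with `curves` (tibble `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `chisq`, `p`, `p_method`,
#'   `groups` (sizes).
#' @export
km_logrank <- function(time, event, group,
                       p_method = c("asymptotic", "permutation"),
                       n_perm = 10000L, max_exhaustive = 100000L) {
  p_method <- match.arg(p_method)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("km_logrank requires exactly 2 non-empty groups")
  if (sum(event) < 1) stop("no events observed")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_names <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- tibble::tibble(group = strata_names, time = fit$time,
                           n_risk = fit$n.risk, n_event = fit$n.event,
                           surv = fit$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  if (p_method == "asymptotic") {
    p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  } else {
    p <- permutation_logrank_p(time, event, group, chisq, n_perm, max_exhaustive)
  }
  structure(list(curves = curves, chisq = chisq, p = p, p_method = p_method,
                 groups = table(group)), class = "nm_km")
}

permutation_logrank_p <- function(time, event, group, obs_chisq,
                                  n_perm, max_exhaustive) {
  g <- as.integer(group) == 1L
  n <- length(g); n1 <- sum(g)
  stat_for <- function(assign) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ assign)
    sd$chisq
  }
  n_comb <- choose(n, n1)
  if (n_comb <= max_exhaustive) {
    combs <- utils::combn(n, n1)
    stats_all <- apply(combs, 2, function(ix) {
      a <- rep(FALSE, n); a[ix] <- TRUE
      stat_for(a)
    })
    mean(stats_all >= obs_chisq - 1e-12)
  } else {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      a <- rep(FALSE, n); a[sample.int(n, n1)] <- TRUE
      if (stat_for(a) >= obs_chisq - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
}

#' @export
print.nm_km <- function(x, ...) {
  cat(sprintf("<nm_km: log-rank chisq %.3f, p = %.4g (%s); groups %s>\n",
              x$chisq, x$p, x$p_method,
              paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", ")))
  invisible(x)
}

#' Cox proportional-hazards fit with likelihood-ratio model p
#'
#' Wraps a partial-likelihood fit: hazard ratios with 95 percent Wald
#' confidence intervals per covariate, per-covariate Wald p, and the model
#' p from the likelihood-ratio test against the null model.
#'
#' @param data data frame / tibble.
#' @param formula right-hand side of covariates, e.g. `~ group + age`.
#' @param time_col,event_col column names of the outcome.
#' @return object of class `nm_cox`; use [generics::tidy()] for per-term
#'   hazard ratios and [generics::glance()] for model-level statistics.
#' @export
cox_ph <- function(data, formula, time_col = "time", event_col = "event") {
  terms_rhs <- stats::delete.response(stats::terms(formula))
  nev <- sum(data[[event_col]])
  ncov <- length(attr(terms_rhs, "term.labels"))
  if (nev < ncov + 1)
    stop(sprintf("too few events (%d) for %d covariates", nev, ncov))
  f <- stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col, ") ",
                                paste(deparse(formula), collapse = "")))
  fit <- tryCatch(survival::coxph(f, data = data),
                  warning = function(w) {
                    if (grepl("infinite|did not converge|beta may be infinite",
                              conditionMessage(w)))
                      stop("Cox fit failed to converge (possible complete separation): ",
                           conditionMessage(w), call. = FALSE)
                    suppressWarnings(survival::coxph(f, data = data))
                  })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tidy_tbl <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "coef"]),
    hr = unname(co[, "exp(coef)"]),
    std_error = unname(co[, "se(coef)"]),
    conf_low = unname(ci[, "lower .95"]),
    conf_high = unname(ci[, "upper .95"]),
    p_wald = unname(co[, "Pr(>|z|)"]))
  p_lrt <- unname(s$logtest["pvalue"])
  structure(list(fit = fit, tidy = tidy_tbl, p_likelihood = p_lrt,
                 n = s$n, n_event = nev, loglik = fit$loglik),
            class = "nm_cox")
}

#' @export
print.nm_cox <- function(x, ...) {
  cat(sprintf("<nm_cox: n = %d, events = %d, likelihood-ratio p = %.4g>\n",
              x$n, x$n_event, x$p_likelihood))
  print(x$tidy)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nm_cox <- function(x, ...) x$tidy

#' @export
glance.nm_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event,
                 p_likelihood = x$p_likelihood,
                 loglik_null = x$loglik[1], loglik = x$loglik[2])
}

#' @export
tidy.nm_km <- function(x, ...) x$curves

#' @export
glance.nm_km <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, p = x$p, p_method = x$p_method)
}

#' Rank-based group comparison with optional FDR adjustment
#'
#' Two-sided Wilcoxon rank-sum for two groups, Kruskal-Wallis for more.
#' When several features are supplied the p values are Benjamini-Hochberg
#' adjusted across the family. Ties use mid-ranks with the normal
#' approximation; the exact test is used for fewer than 20 observations
#' per group when there are no ties.
#'
#' @param data tibble with a `value` column, a `group` column and
#'   optionally a `feature` column defining the family.
#' @param test `"wilcoxon"` or `"kruskal"`.
#' @param adjust `"none"` or `"fdr"` (Benjamini-Hochberg).
#' @return tibble with `feature`, `test`, `p`, `p_adj`.
#' @export
group_compare <- function(data, test = c("wilcoxon", "kruskal"),
                          adjust = c("none", "fdr")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!"feature" %in% names(data)) data$feature <- "value"
  out <- lapply(split(data, data$feature), function(d) {
    g <- droplevels(as.factor(d$group))
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    if (any(table(g) == 0)) stop("each group must be non-empty")
    p <- if (test == "wilcoxon") {
      if (nlevels(g) != 2L) stop("wilcoxon requires exactly 2 groups")
      suppressWarnings(stats::wilcox.test(d$value ~ g)$p.value)
    } else {
      stats::kruskal.test(d$value, g)$p.value
    }
    tibble::tibble(feature = d$feature[1], test = test, p = p)
  })
  out <- dplyr::bind_rows(out)
  out$p_adj <- if (adjust == "fdr") stats::p.adjust(out$p, method = "BH") else out$p
  out
}

#' Pearson correlation with t-test p value
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return tibble with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
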