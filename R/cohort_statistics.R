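# Cohort-level statistics for compartment-scored marker expression:
# clinicopathological categorisation, paired and two-group comparisons,
# logistic regression with ROC AUC, and Cox proportional-hazards models for
# overall and disease-free survival.

#' Canonical marker measurement columns
#'
#' The 12 per-patient measurements: percent-positive for each marker
#' (CXCR3/CXCR4/CXCR7) x compartment (nucleus/cytoplasm) x region
#' (glandular/interstitial).
#'
#' @param markers,compartments,regions optional subsets.
#' @return character vector of column names like `"cxcr3_nuc_gland"`.
#' @export
marker_columns <- function(markers = c("cxcr3", "cxcr4", "cxcr7"),
                           compartments = c("nuc", "cyt"),
                           regions = c("gland", "inter")) {
  as.vector(t(outer(markers, as.vector(t(outer(compartments, regions, paste,
                                               sep = "_"))), paste, sep = "_")))
}

#' @noRd
cohort_columns <- function() {
  c("patient_id", "sex", "age", "differentiation", "invasion",
    "t_score", "n_score", "tnm", "os_months", "os_event",
    "dfs_months", "dfs_event", marker_columns())
}

#' Validate a cohort table against the expected schema
#'
#' @param cohort data frame, one row per patient.
#' @return the cohort, invisibly, or a validation error naming the first
#'   missing column.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) err_validation("cohort must be a data frame")
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing))
    err_validation("cohort table is missing column \"%s\"", missing[1])
  if (any(cohort$os_months < 0, na.rm = TRUE) ||
      any(cohort$dfs_months < 0, na.rm = TRUE))
    err_validation("survival times must be non-negative")
  for (mc in marker_columns()) {
    v <- cohort[[mc]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      err_validation("marker column \"%s\" must lie in [0, 100]", mc)
  }
  invisible(cohort)
}

# ---- categorisation -------------------------------------------------------

#' Dichotomise tumour-extent (T) scores as T1-2 vs T3-4
#' @param t_score integer vector with values in 1..4.
#' @return factor with levels `"T1-2"`, `"T3-4"`.
#' @export
categorize_t <- function(t_score) {
  if (any(is.na(t_score)) || !all(t_score %in% 1:4))
    err_validation("t_score values must be in {1, 2, 3, 4}")
  factor(ifelse(t_score <= 2, "T1-2", "T3-4"), levels = c("T1-2", "T3-4"))
}

#' Dichotomise nodal (N) scores as node-negative (N = 0) vs node-positive
#' @param n_score non-negative integer vector.
#' @return factor with levels `"node_negative"`, `"node_positive"`.
#' @export
categorize_n <- function(n_score) {
  if (any(is.na(n_score)) || any(n_score < 0) || any(n_score != round(n_score)))
    err_validation("n_score values must be non-negative integers")
  factor(ifelse(n_score == 0, "node_negative", "node_positive"),
         levels = c("node_negative", "node_positive"))
}

#' Dichotomise TNM stage as early (0-2) vs advanced (3-4)
#' @param tnm integer vector with values in 0..4.
#' @return factor with levels `"early"`, `"advanced"`.
#' @export
categorize_tnm <- function(tnm) {
  if (any(is.na(tnm)) || !all(tnm %in% 0:4))
    err_validation("tnm values must be in {0, 1, 2, 3, 4}")
  factor(ifelse(tnm <= 2, "early", "advanced"), levels = c("early", "advanced"))
}

# ---- comparisons ----------------------------------------------------------

#' Paired two-sided comparison of two per-patient measurements
#'
#' Pairs with a missing member are dropped. The Wilcoxon signed-rank test is
#' exact for n <= 25 complete pairs without ties or zero differences, and
#' uses the continuity-corrected normal approximation otherwise. All-zero
#' differences (and zero-variance differences under the paired t) are
#' degenerate: the result is flagged and carries no significance claim.
#'
#' @param x,y numeric vectors of equal length (one value per patient).
#' @param method `"wilcoxon"` (signed-rank) or `"paired_t"`.
#' @return list of class `ihc_comparison`: `method`, `n`, `statistic`,
#'   `p_value`, `estimate` (means of x and y over complete pairs), `flag`.
#' @export
compare_paired <- function(x, y, method = c("wilcoxon", "paired_t")) {
  method <- match.arg(method)
  if (length(x) != length(y)) err_format("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) err_insufficient("fewer than 3 complete pairs (n = %d)", n)
  est <- c(mean_x = mean(x), mean_y = mean(y))
  d <- x - y
  if (method == "wilcoxon") {
    if (all(d == 0))
      return(comparison_result(method, n, statistic = 0, p_value = NA_real_,
                               estimate = est, flag = "degenerate_all_zero"))
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                       correct = TRUE))
    comparison_result(method, n, unname(wt$statistic), wt$p.value, est, "ok")
  } else {
    if (sd(d) == 0)
      return(comparison_result(method, n, statistic = NA_real_,
                               p_value = NA_real_, estimate = est,
                               flag = "degenerate_zero_variance"))
    tt <- t.test(x, y, paired = TRUE)
    comparison_result(method, n, unname(tt$statistic), tt$p.value, est, "ok")
  }
}

#' Two-sided comparison of a measurement between two patient groups
#'
#' Mann-Whitney U (exact when the pooled n is <= 25 and tie-free, else the
#' continuity-corrected normal approximation) or Welch's t test.
#'
#' @param values numeric per-patient measurement.
#' @param groups a two-level factor (or vector coercible to one) of the same
#'   length.
#' @param method `"mann_whitney"` or `"welch_t"`.
#' @return list of class `ihc_comparison` with per-group sizes and means.
#' @export
compare_groups <- function(values, groups, method = c("mann_whitney", "welch_t")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups[!is.na(groups)])) != 2)
    err_validation("groups must have exactly two levels")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (length(g1) < 3 || length(g2) < 3)
    err_insufficient("each group needs >= 3 observations (got %d and %d)",
                     length(g1), length(g2))
  est <- setNames(c(mean(g1), mean(g2)), levels(groups))
  sizes <- setNames(c(length(g1), length(g2)), levels(groups))
  if (method == "mann_whitney") {
    exact <- (length(g1) + length(g2)) <= 25 && !any(duplicated(values))
    wt <- suppressWarnings(wilcox.test(g1, g2, exact = exact, correct = TRUE))
    res <- comparison_result(method, length(values), unname(wt$statistic),
                             wt$p.value, est, "ok")
  } else {
    tt <- t.test(g1, g2)
    res <- comparison_result(method, length(values), unname(tt$statistic),
                             tt$p.value, est, "ok")
  }
  res$sizes <- sizes
  res
}

#' @noRd
comparison_result <- function(method, n, statistic, p_value, estimate, flag) {
  structure(list(method = method, n = n, statistic = statistic,
                 p_value = p_value, estimate = estimate, flag = flag),
            class = "ihc_comparison")
}

#' @export
print.ihc_comparison <- function(x, ...) {
  cat(sprintf("<ihc_comparison> %s, n = %d, statistic = %s, p = %s [%s]\n",
              x$method, x$n, format(x$statistic), format(x$p_value), x$flag))
  invisible(x)
}

# ---- ROC / logistic -------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank statistic of the scores: the probability that a random positive
#' outranks a random negative, with ties counting one half —
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`. Computed via midranks, so
#' it agrees exactly with the all-pairs count.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (0/1, logical, or a two-level factor where
#'   the second level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) err_format("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) err_validation("labels must be binary")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) err_validation("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties exactly
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic regression with in-sample ROC AUC
#'
#' Maximum-likelihood logistic fit of a binary outcome on the selected
#' predictors; the AUC is apparent (computed on in-sample fitted
#' probabilities). Complete separation is detected and flagged instead of
#' silently reporting diverged coefficients.
#'
#' @param outcome binary vector (0/1, logical, or two-level factor).
#' @param predictors data frame (or matrix) of numeric predictor columns.
#' @return list of class `ihc_logistic`: `coefficients` (data frame with
#'   estimate, std_error, z, p_value per term), `auc`, `n`, `separation`.
#' @export
fit_logistic_auc <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) err_validation("outcome must be binary")
  ok <- !is.na(outcome) & complete.cases(predictors)
  outcome <- outcome[ok]
  predictors <- predictors[ok, , drop = FALSE]
  if (length(unique(outcome)) < 2)
    err_validation("both outcome classes must be present")
  if (length(outcome) <= ncol(predictors) + 1)
    err_insufficient("need n > #predictors + 1")
  dat <- data.frame(.y = outcome, predictors)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      std_error = cf[, 2], z = cf[, 3], p_value = cf[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 auc = roc_auc(stats::fitted(fit), outcome),
                 n = length(outcome), separation = sep),
            class = "ihc_logistic")
}

#' @export
print.ihc_logistic <- function(x, ...) {
  cat(sprintf("<ihc_logistic> n = %d, AUC = %.3f%s\n", x$n, x$auc,
              if (x$separation) " [complete separation flagged]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# ---- Cox ------------------------------------------------------------------

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' 95% confidence intervals on the log scale.
#'
#' @param data data frame holding the time, event and covariate columns.
#' @param time,event column names of the follow-up time and event indicator.
#' @param covariates character vector of covariate column names.
#' @return list of class `ihc_cox`: `table` (data frame with `term`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `log_hr`, `se`), `n`, `n_events`,
#'   `flag` (`"ok"` or `"low_events"` below 10 events).
#' @export
fit_cox <- function(data, time, event, covariates) {
  for (col in c(time, event, covariates))
    if (!col %in% names(data)) err_validation("missing column \"%s\"", col)
  dat <- data[, c(time, event, covariates)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  ev <- dat[[event]]
  if (sum(ev) == 0) err_validation("no events observed")
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) < 2)
      err_validation("covariate \"%s\" is constant", cv)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  sf <- summary(fit)
  tab <- data.frame(term = rownames(sf$coefficients),
                    hr = sf$coefficients[, "exp(coef)"],
                    ci_low = sf$conf.int[, "lower .95"],
                    ci_high = sf$conf.int[, "upper .95"],
                    p_value = sf$coefficients[, "Pr(>|z|)"],
                    log_hr = sf$coefficients[, "coef"],
                    se = sf$coefficients[, "se(coef)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n = nrow(dat), n_events = sum(ev),
                 flag = if (sum(ev) < 10) "low_events" else "ok"),
            class = "ihc_cox")
}

#' @export
print.ihc_cox <- function(x, ...) {
  cat(sprintf("<ihc_cox> n = %d, events = %d [%s]\n", x$n, x$n_events, x$flag))
  print(x$table, digits = 3)
  invisible(x)
}

# ---- full analysis --------------------------------------------------------

#' Run the full cohort analysis program
#'
#' Produces the three report tables of a compartment-expression biomarker
#' study:
#' * `paired` — 12 paired comparisons: nucleus vs cytoplasm within each
#'   marker x region, and glandular vs interstitial within each
#'   marker x compartment;
#' * `groups` — each of the 12 measurements compared between the binary
#'   clinicopathological categories (differentiation low/high, invasion
#'   low/high, T1-2 vs T3-4, N0 vs N>0, early vs advanced TNM), plus one
#'   multivariate logistic fit with apparent AUC per category using the six
#'   glandular measurements as predictors;
#' * `cox` — multivariate Cox models for OS and DFS with sex, dichotomised
#'   T and N stage, and the six glandular measurements (interstitial
#'   measurements are excluded to limit overfitting at cohort scale).
#'
#' Analyses that cannot run (too few observations, single-class outcomes)
#' are reported as flagged rows; the rest of the program continues.
#'
#' @param cohort validated cohort data frame (see [validate_cohort()]).
#' @param paired_method,group_method test choices passed to
#'   [compare_paired()] / [compare_groups()].
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values added per table.
#' @return list of class `ihc_report` with data frames `paired`, `groups`,
#'   `logistic`, `cox`.
#' @export
run_full_analysis <- function(cohort,
                              paired_method = c("wilcoxon", "paired_t"),
                              group_method = c("mann_whitney", "welch_t"),
                              adjust = c("none", "BH")) {
  validate_cohort(cohort)
  paired_method <- match.arg(paired_method)
  group_method <- match.arg(group_method)
  adjust <- match.arg(adjust)
  markers <- c("cxcr3", "cxcr4", "cxcr7")

  # (a) paired comparisons
  paired <- list()
  add_paired <- function(label, xcol, ycol) {
    res <- try_analysis(compare_paired(cohort[[xcol]], cohort[[ycol]],
                                       paired_method))
    paired[[length(paired) + 1]] <<- data.frame(
      comparison = label, x = xcol, y = ycol,
      n = res$n %||% NA_integer_,
      mean_x = unname(res$estimate[1]) %||% NA_real_,
      mean_y = unname(res$estimate[2]) %||% NA_real_,
      statistic = res$statistic %||% NA_real_,
      p_value = res$p_value %||% NA_real_,
      flag = res$flag, stringsAsFactors = FALSE)
  }
  for (m in markers) for (rg in c("gland", "inter"))
    add_paired(sprintf("%s %s: nucleus vs cytoplasm", toupper(m), rg),
               sprintf("%s_nuc_%s", m, rg), sprintf("%s_cyt_%s", m, rg))
  for (m in markers) for (cp in c("nuc", "cyt"))
    add_paired(sprintf("%s %s: glandular vs interstitial", toupper(m), cp),
               sprintf("%s_%s_gland", m, cp), sprintf("%s_%s_inter", m, cp))
  paired <- do.call(rbind, paired)

  # (b) group comparisons + logistic/AUC per categorisation
  cats <- list(
    differentiation = median_split(cohort$differentiation, c("low", "high")),
    invasion = median_split(cohort$invasion, c("low", "high")),
    t_stage = categorize_t(cohort$t_score),
    n_stage = categorize_n(cohort$n_score),
    tnm_stage = categorize_tnm(cohort$tnm))
  groups <- list(); logistic <- list()
  gland_cols <- marker_columns(regions = "gland")
  for (cat_name in names(cats)) {
    g <- cats[[cat_name]]
    for (mc in marker_columns()) {
      res <- try_analysis(compare_groups(cohort[[mc]], g, group_method))
      groups[[length(groups) + 1]] <- data.frame(
        category = cat_name, measurement = mc,
        n = res$n %||% NA_integer_,
        mean_group1 = unname(res$estimate[1]) %||% NA_real_,
        mean_group2 = unname(res$estimate[2]) %||% NA_real_,
        statistic = res$statistic %||% NA_real_,
        p_value = res$p_value %||% NA_real_,
        flag = res$flag, stringsAsFactors = FALSE)
    }
    lres <- try_analysis(fit_logistic_auc(g, cohort[, gland_cols]))
    logistic[[length(logistic) + 1]] <- if (inherits(lres, "ihc_logistic")) {
      cf <- lres$coefficients[lres$coefficients$term != "(Intercept)", ]
      data.frame(category = cat_name, term = cf$term, estimate = cf$estimate,
                 p_value = cf$p_value, auc = lres$auc, n = lres$n,
                 flag = if (lres$separation) "separation" else "ok",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(category = cat_name, term = NA_character_,
                 estimate = NA_real_, p_value = NA_real_, auc = NA_real_,
                 n = NA_integer_, flag = lres$flag, stringsAsFactors = FALSE)
    }
  }
  groups <- do.call(rbind, groups)
  logistic <- do.call(rbind, logistic)

  # (c) Cox OS / DFS with sex, T, N + glandular markers
  cox_dat <- cohort
  cox_dat$sex_male <- as.integer(cohort$sex == "male")
  cox_dat$t34 <- as.integer(categorize_t(cohort$t_score) == "T3-4")
  cox_dat$node_pos <- as.integer(categorize_n(cohort$n_score) == "node_positive")
  covs <- c("sex_male", "t34", "node_pos", gland_cols)
  cox <- list()
  for (ep in c("OS", "DFS")) {
    tm <- if (ep == "OS") "os_months" else "dfs_months"
    evc <- if (ep == "OS") "os_event" else "dfs_event"
    res <- try_analysis(fit_cox(cox_dat, tm, evc, covs))
    cox[[length(cox) + 1]] <- if (!is.null(res$table)) {
      data.frame(endpoint = ep, res$table,
                 n = res$n, n_events = res$n_events, flag = res$flag,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(endpoint = ep, term = NA_character_, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 log_hr = NA_real_, se = NA_real_, n = NA_integer_,
                 n_events = NA_integer_, flag = res$flag,
                 stringsAsFactors = FALSE)
    }
  }
  cox <- do.call(rbind, cox)

  if (adjust == "BH") {
    paired$p_adjusted <- stats::p.adjust(paired$p_value, "BH")
    groups$p_adjusted <- stats::p.adjust(groups$p_value, "BH")
  }
  structure(list(paired = paired, groups = groups, logistic = logistic,
                 cox = cox), class = "ihc_report")
}

# Median split for ordinal scores: values <= median are "low" (ties to low).
#' @noRd
median_split <- function(x, labels) {
  med <- median(x, na.rm = TRUE)
  factor(ifelse(x <= med, labels[1], labels[2]), levels = labels)
}

# Capture insufficient-data / validation conditions as flagged pseudo-results
# so one failed analysis never aborts the rest of the report.
#' @noRd
try_analysis <- function(expr) {
  tryCatch(expr,
           ihcscore_error = function(e)
             list(flag = paste0("skipped: ", conditionMessage(e))),
           error = function(e)
             list(flag = paste0("failed: ", conditionMessage(e))))
}

#' @export
print.ihc_report <- function(x, ...) {
  cat("<ihc_report>\n")
  cat(sprintf("  paired comparisons: %d rows\n", nrow(x$paired)))
  cat(sprintf("  group comparisons:  %d rows\n", nrow(x$groups)))
  cat(sprintf("  logistic models:    %d rows\n", nrow(x$logistic)))
  cat(sprintf("  cox models:         %d rows\n", nrow(x$cox)))
  invisible(x)
}
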