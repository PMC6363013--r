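#' Kaplan-Meier estimate with median survival and 95% CI
#'
#' Product-limit estimate of the survival function with log-log
#' (Greenwood) confidence intervals. The median is the smallest time at
#' which S(t) <= 0.5, NA if the curve never reaches 0.5.
#'
#' @param time numeric survival times (months).
#' @param event logical/0-1 event indicators (TRUE = death observed).
#' @return list with `fit` (a `survfit` object), `median`, `lcl`, `ucl`.
#' @export
kmEstimate <- function(time, event) {
    fit <- survival::survfit(
        survival::Surv(time, as.integer(as.logical(event))) ~ 1,
        conf.type = "log-log", conf.int = 0.95)
    tb <- summary(fit)$table
    list(fit = fit, median = unname(tb["median"]),
         lcl = unname(tb["0.95LCL"]), ucl = unname(tb["0.95UCL"]))
}

#' Two-group log-rank test
#'
#' @param time numeric survival times.
#' @param event logical/0-1 event indicators.
#' @param group two-level factor (or coercible).
#' @return list with `chisq` (1 df statistic) and `p`.
#' @export
logrankTest <- function(time, event, group) {
    group <- droplevels(factor(group))
    if (nlevels(group) != 2L) stop("exactly two non-empty groups required")
    event <- as.integer(as.logical(event))
    if (sum(event) == 0L)
        stop("log-rank test undefined: no events observed")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- unname(sd$chisq)
    list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Bonferroni adjustment with an explicit test count
#'
#' @param p numeric p-values.
#' @param m number of simultaneous tests (>= length(p)).
#' @return Adjusted p-values, `pmin(1, m * p)`.
#' @export
bonferroniAdjust <- function(p, m) {
    if (m < length(p)) stop("m must be at least the number of p-values")
    pmin(1, m * p)
}

# Shared KM/log-rank machinery for a two-group split.
fitStratum <- function(time, event, groups, feature, cutoff, orientation,
                       nTests, horizon) {
    event <- as.integer(as.logical(event))
    lr <- logrankTest(time, event, groups)
    fit <- survival::survfit(survival::Surv(time, event) ~ groups,
                             conf.type = "log-log", conf.int = 0.95)
    tb <- summary(fit)$table
    med <- data.frame(group = sub("^groups=", "", rownames(tb)),
                      n = unname(tb[, "records"]),
                      median = unname(tb[, "median"]),
                      lcl = unname(tb[, "0.95LCL"]),
                      ucl = unname(tb[, "0.95UCL"]))
    sAt <- NULL
    if (!is.null(horizon)) {
        sm <- summary(fit, times = horizon, extend = TRUE)
        sAt <- data.frame(group = sub("^groups=", "", sm$strata),
                          time = sm$time, survival = sm$surv)
    }
    new("StratumResult", feature = feature, cutoff = cutoff,
        orientation = orientation, groups = groups, fit = fit,
        medians = med, logrankP = lr$p,
        adjustedP = bonferroniAdjust(lr$p, nTests), survivalAt = sAt)
}

#' Dichotomize a cohort at a fixed cutoff and compare survival
#'
#' Assigns group1 = feature value >= cutoff, group2 = value < cutoff, then
#' fits per-group Kaplan-Meier curves and the two-group log-rank test, with
#' Bonferroni adjustment for `nTests` simultaneous tests.
#'
#' @param clinical data.frame with time, event (see [loadClinical()]).
#' @param values numeric feature values, one per patient (same order).
#' @param cutoff numeric cutoff.
#' @param feature character label for reporting.
#' @param nTests Bonferroni multiplicity (default 1).
#' @param horizon optional time (months) at which per-group survival
#'   probabilities are reported.
#' @return A [StratumResult-class].
#' @export
stratifyCohort <- function(clinical, values, cutoff,
                           feature = "feature", nTests = 1L,
                           horizon = NULL) {
    stopifnot(length(values) == nrow(clinical))
    groups <- factor(ifelse(values >= cutoff, "group1", "group2"),
                     levels = c("group1", "group2"))
    if (any(tabulate(groups, 2L) == 0L))
        stop("degenerate-split error: cutoff leaves one group empty")
    fitStratum(clinical$time, clinical$event, groups, feature, cutoff,
               ">= cutoff is group1", nTests, horizon)
}

#' MGMT-only survival stratification
#'
#' Compares methylated vs unmethylated patients (unknown MGMT excluded).
#'
#' @inheritParams stratifyCohort
#' @param clinical data.frame with time, event, mgmt.
#' @return A [StratumResult-class].
#' @export
stratifyMgmt <- function(clinical, nTests = 1L, horizon = NULL) {
    known <- clinical$mgmt %in% c("methylated", "unmethylated")
    cl <- clinical[known, , drop = FALSE]
    groups <- factor(ifelse(cl$mgmt == "methylated", "methylated",
                            "unmethylated"),
                     levels = c("methylated", "unmethylated"))
    if (any(tabulate(groups, 2L) == 0L))
        stop("degenerate-split error: one MGMT group is empty")
    fitStratum(cl$time, cl$event, groups, "MGMT", NA_real_,
               "methylated is group1", nTests, horizon)
}

#' Combined MGMT + radiomic-feature stratification
#'
#' Among patients with known MGMT status, group1 is methylated AND feature
#' value < cutoff (the favorable combination); group2 is everyone else
#' with known MGMT. Kaplan-Meier curves, log-rank p and the survival
#' probability at a requested horizon are reported.
#'
#' @inheritParams stratifyCohort
#' @param clinical data.frame with time, event, mgmt.
#' @param horizon time in months for the reported survival probability
#'   (default 43).
#' @return A [StratumResult-class].
#' @export
combineMgmt <- function(clinical, values, cutoff, feature = "feature",
                        nTests = 1L, horizon = 43) {
    stopifnot(length(values) == nrow(clinical))
    known <- clinical$mgmt %in% c("methylated", "unmethylated")
    cl <- clinical[known, , drop = FALSE]
    v <- values[known]
    g1 <- cl$mgmt == "methylated" & v < cutoff
    groups <- factor(ifelse(g1, "methylated+low", "rest"),
                     levels = c("methylated+low", "rest"))
    if (any(tabulate(groups, 2L) == 0L))
        stop("degenerate-split error: empty combined group")
    fitStratum(cl$time, cl$event, groups,
               paste0("MGMT+", feature), cutoff,
               "methylated & feature < cutoff is group1", nTests, horizon)
}

#' Frozen-cutoff external validation
#'
#' Applies cutoffs frozen on the training cohort to a validation cohort
#' with no re-optimization: group assignment depends only on the sign of
#' (value - cutoff). `mode` picks the training-optimal (Youden) or the
#' training-median cutoff column. Bonferroni multiplicity is the number of
#' features carried forward.
#'
#' @param clinical validation data.frame (time, event, mgmt).
#' @param values patients-by-features matrix of validation feature values.
#' @param cutoffs data.frame with columns feature, optimal, median (from
#'   [runTraining()]).
#' @param mode "training_optimal" or "training_median".
#' @param horizon optional reporting horizon (months).
#' @return Named list of [StratumResult-class], one per carried feature.
#' @export
validateExternal <- function(clinical, values, cutoffs,
                             mode = c("training_optimal",
                                      "training_median"),
                             horizon = NULL) {
    mode <- match.arg(mode)
    values <- featureMatrix(values)
    if (!all(cutoffs$feature %in% colnames(values)))
        stop("configuration error: missing frozen cutoff feature(s) in ",
             "validation values")
    col <- if (mode == "training_optimal") "optimal" else "median"
    if (!col %in% names(cutoffs))
        stop("configuration error: cutoffs table lacks '", col, "'")
    m <- nrow(cutoffs)
    out <- list()
    for (k in seq_len(m)) {
        ft <- cutoffs$feature[k]
        out[[ft]] <- stratifyCohort(clinical, values[, ft],
                                    cutoff = cutoffs[[col]][k],
                                    feature = ft, nTests = m,
                                    horizon = horizon)
    }
    out
}

#' Tabulate stratification results
#'
#' Flattens a list of [StratumResult-class] into the reporting table used
#' throughout the package: per-group median survivals with 95% CIs, raw
#' and Bonferroni-adjusted log-rank p-values and group sizes.
#'
#' @param strata list of [StratumResult-class].
#' @return data.frame, one row per stratification.
#' @export
strataTable <- function(strata) {
    if (is(strata, "StratumResult")) strata <- list(strata)
    do.call(rbind, lapply(strata, function(s) {
        md <- s@medians
        data.frame(feature = s@feature, cutoff = s@cutoff,
                   group1 = md$group[1], n1 = md$n[1],
                   median1 = md$median[1], lcl1 = md$lcl[1],
                   ucl1 = md$ucl[1],
                   group2 = md$group[2], n2 = md$n[2],
                   median2 = md$median[2], lcl2 = md$lcl[2],
                   ucl2 = md$ucl[2],
                   p = s@logrankP, p_adjusted = s@adjustedP,
                   stringsAsFactors = FALSE)
    }))
}
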