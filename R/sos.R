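#' Naive signature outcome separation (SOS)
#'
#' Univariate Cox proportional hazards fit of survival on the binary
#' patients-up / patients-down grouping. The hazard ratio is up vs down
#' (HR > 1: detection of the signature associates with worse outcome).
#' The reported p-value is the log-rank test; the Wald p of the Cox
#' coefficient is also returned. Ties are handled with the Efron
#' approximation. Unassigned samples are dropped.
#'
#' @param groups A `group_assignment` from [split_samples()].
#' @param survival_df Data frame with `sample_id`, `time`, `event` (0/1)
#'   and optionally `cohort`.
#' @param cohort Cohort label recorded on the result.
#' @param exemplar Exemplar id recorded on the result.
#' @return A one-row data frame of class `sos_result`: cohort, exemplar,
#'   n_up, n_down, hazard_ratio, p (log-rank), wald_p, model, flags.
#' @export
fit_sos <- function(groups, survival_df, cohort = "cohort",
                    exemplar = "exemplar") {
  d <- .sos_data(groups, survival_df)
  flag <- ""
  if (nrow(d) == 0L || length(unique(d$group)) < 2L) {
    return(.sos_row(cohort, exemplar, d, NA, NA, NA, "naive", "no_groups"))
  }
  ev <- tapply(d$event, d$group, sum)
  if (any(ev < 2)) flag <- "unstable_few_events"
  if (any(ev == 0)) {
    return(.sos_row(cohort, exemplar, d, NA, NA, NA, "naive",
                    "unstable_zero_events"))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ group, data = d,
                    ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ group, data = d,
                        ties = "efron")
      )
      attr(f, "sep_warn") <- TRUE
      f
    }
  )
  if (isTRUE(attr(fit, "sep_warn")) &&
      abs(stats::coef(fit)[1]) > 10) {
    flag <- paste0(flag, ";separation_fallback")
  }
  hr <- unname(exp(stats::coef(fit)["groupup"]))
  wald_p <- summary(fit)$coefficients["groupup", "Pr(>|z|)"]
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  .sos_row(cohort, exemplar, d, hr, logrank_p, wald_p, "naive", flag)
}

#' Subtype-corrected signature outcome separation
#'
#' Multivariate Cox fit with the up/down group indicator plus the published
#' subtype as a categorical covariate (reference level = largest subtype).
#' The reported p is the Wald p of the group coefficient (the log-rank test
#' cannot adjust for covariates). With a single subtype level the model
#' reduces exactly to the naive fit.
#'
#' @inheritParams fit_sos
#' @param subtypes Named character vector (names = sample ids) of subtype
#'   labels, or a `subtype` column in `survival_df`.
#' @return A one-row `sos_result` data frame with `model =
#'   "subtype_corrected"`.
#' @export
fit_subtype_corrected_sos <- function(groups, survival_df, subtypes = NULL,
                                      cohort = "cohort",
                                      exemplar = "exemplar") {
  d <- .sos_data(groups, survival_df)
  if (is.null(subtypes)) {
    if (!"subtype" %in% colnames(survival_df)) {
      stop("no subtype information supplied")
    }
    subtypes <- stats::setNames(survival_df$subtype, survival_df$sample_id)
  }
  d$subtype <- as.character(subtypes[d$sample_id])
  d <- d[!is.na(d$subtype), , drop = FALSE]
  if (nrow(d) == 0L || length(unique(d$group)) < 2L) {
    return(.sos_row(cohort, exemplar, d, NA, NA, NA, "subtype_corrected",
                    "no_groups"))
  }
  if (length(unique(d$subtype)) < 2L) {
    res <- fit_sos(groups, survival_df, cohort, exemplar)
    res$model <- "subtype_corrected"
    res$p <- res$wald_p   # covariate-adjusted family reports Wald p
    return(res)
  }
  ref <- names(which.max(table(d$subtype)))
  d$subtype <- stats::relevel(factor(d$subtype), ref = ref)
  # collinearity guard: group constant within every subtype level
  tab <- table(d$subtype, d$group)
  if (all(apply(tab, 1, function(r) sum(r > 0) <= 1L))) {
    return(.sos_row(cohort, exemplar, d, NA, NA, NA, "subtype_corrected",
                    "collinear_subtype"))
  }
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group + subtype, data = d,
                    ties = "efron")
  )
  hr <- unname(exp(stats::coef(fit)["groupup"]))
  wald_p <- summary(fit)$coefficients["groupup", "Pr(>|z|)"]
  .sos_row(cohort, exemplar, d, hr, wald_p, wald_p, "subtype_corrected", "")
}

.sos_data <- function(groups, survival_df) {
  stopifnot(inherits(groups, "group_assignment"))
  keep <- groups$label %in% c("up", "down")
  d <- data.frame(sample_id = groups$sample_ids[keep],
                  group = unname(groups$label[keep]),
                  stringsAsFactors = FALSE)
  d <- merge(d, survival_df, by = "sample_id")
  d$group <- factor(d$group, levels = c("down", "up"))
  d
}

.sos_row <- function(cohort, exemplar, d, hr, p, wald_p, model, flag) {
  out <- data.frame(
    cohort = cohort, exemplar = exemplar,
    n_up = sum(d$group == "up"), n_down = sum(d$group == "down"),
    hazard_ratio = hr, p = p, wald_p = wald_p,
    model = model, flag = flag, stringsAsFactors = FALSE
  )
  class(out) <- c("sos_result", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up over the family of tested exemplar-cohort pairs.
#' NA p-values are carried through as NA and do not count toward the
#' family size.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Significance tier flags
#'
#' Report-level tiers used for result tables: `"*"` for p < 0.05, `"**"`
#' for p < 0.001, `""` otherwise.
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @return Character vector of flags.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "")))
}

#' Kaplan-Meier summary per group
#'
#' Product-limit estimates with at-risk counts at event times, one block
#' per group.
#'
#' @inheritParams fit_sos
#' @return Data frame: group, time, n_risk, n_event, survival.
#' @export
km_summary <- function(groups, survival_df) {
  d <- .sos_data(groups, survival_df)
  if (nrow(d) == 0L) stop("no assigned samples with survival data")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(levels(d$group)[1], length(sm$time))
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  data.frame(
    group = grp, time = sm$time, n_risk = sm$n.risk,
    n_event = sm$n.event, survival = sm$surv,
    stringsAsFactors = FALSE
  )
}
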