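#' Build a survival dataset from a clinical table
#'
#' Restricts to responders (non-null days to recurrence). All non-null
#' entries are treated as observed events unless the clinical table carries
#' an `event` column (from a generator with censoring enabled).
#'
#' @param clinical clinical table.
#' @return `data.frame` with `sample_id`, `time` (days, positive), `event`
#'   (logical), `subtype`.
#' @export
as_survival_dataset <- function(clinical) {
  keep <- clinical$responder & !is.na(clinical$days_to_recurrence)
  assert_that(any(keep), "no responders with non-null days to recurrence")
  d <- clinical[keep, , drop = FALSE]
  ev <- if ("event" %in% names(d)) as.logical(d$event) else rep(TRUE, nrow(d))
  ev[is.na(ev)] <- TRUE
  out <- data.frame(sample_id = d$sample_id,
                    time = pmax(1L, d$days_to_recurrence),
                    event = ev,
                    subtype = d$subtype,
                    stringsAsFactors = FALSE)
  assert_that(all(out$time > 0), "non-positive survival times")
  out
}

#' Split samples into high and low metagene groups at the cohort median
#'
#' Samples are sorted ascending by score (ties broken by sample ID); the
#' first `ceiling(n/2)` form the "low" group, the rest the "high" group,
#' so with odd `n` the median sample goes to "low". The split is meant to
#' be computed on the full cohort before any restriction to responders.
#'
#' @param scores named numeric scores.
#' @return named factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  ids <- names(scores)
  assert_that(!is.null(ids) && length(scores) >= 2,
              "need >= 2 named scores")
  assert_that(all(is.finite(scores)), "non-finite score")
  ord <- order(unclass(scores), ids)
  n_low <- ceiling(length(scores) / 2)
  lab <- rep("high", length(scores))
  lab[ord[seq_len(n_low)]] <- "low"
  factor(stats::setNames(lab, ids), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group and the two-sample log-rank
#' chi-squared statistic (1 df) with its p-value.
#'
#' @param data survival dataset from [as_survival_dataset].
#' @param groups factor with exactly two levels, named by sample ID or
#'   aligned with `data` rows.
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p`, and the per-group observed/expected table; class `km_logrank`.
#' @export
km_logrank <- function(data, groups) {
  g <- align_groups(data, groups)
  assert_that(nlevels(g) == 2 && all(table(g) > 0),
              "need exactly 2 non-empty groups")
  ev_by_group <- tapply(data$event, g, sum)
  if (any(ev_by_group == 0))
    warning("a group has zero events; log-rank statistic may be degenerate")
  df_fit <- data.frame(time = data$time, event = as.integer(data$event), g = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df_fit)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df_fit)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, chisq = unname(sd$chisq), df = 1L, p = p,
                 observed = sd$obs, expected = sd$exp,
                 groups = levels(g)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> groups %s vs %s: chi-squared = %.4g (1 df), P = %.4g\n",
              x$groups[1], x$groups[2], x$chisq, x$p))
  invisible(x)
}

align_groups <- function(data, groups) {
  if (!is.null(names(groups))) {
    idx <- match(data$sample_id, names(groups))
    assert_that(!anyNA(idx), "group labels missing for some samples")
    groups <- groups[idx]
  } else {
    assert_that(length(groups) == nrow(data),
                "groups must be named or match the dataset length")
  }
  droplevels(factor(groups))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit of days to recurrence on a single continuous
#' covariate, with the Efron approximation for tied event times.
#'
#' @param data survival dataset from [as_survival_dataset].
#' @param covariate numeric vector, named by sample ID or aligned with
#'   `data` rows.
#' @return a `cox_fit`: `terms` data.frame (term, coef, se, hr, ci_lo,
#'   ci_hi, p) and `lrt` list (stat, df, p).
#' @export
cox_univariate <- function(data, covariate) {
  if (!is.null(names(covariate))) {
    idx <- match(data$sample_id, names(covariate))
    assert_that(!anyNA(idx), "covariate values missing for some samples")
    covariate <- covariate[idx]
  }
  assert_that(length(covariate) == nrow(data), "covariate length mismatch")
  assert_that(all(is.finite(covariate)), "non-finite covariate")
  assert_that(sum(data$event) >= 2, "need at least 2 events")
  assert_that(stats::sd(covariate) > 0,
              "degenerate design: covariate has zero variance")
  df_fit <- data.frame(time = data$time, event = as.integer(data$event),
                       x = as.numeric(covariate))
  fit <- fit_coxph(survival::Surv(time, event) ~ x, df_fit)
  make_cox_fit(fit, term_names = "covariate")
}

#' Multivariate Cox regression with deviation-coded subtype contrasts
#'
#' Fits days to recurrence on the metagene (continuous; standardized to
#' unit variance by default) plus the tumor subtype under sum-to-zero
#' (deviation) coding, so each subtype coefficient is the contrast between
#' that subtype's mean log-hazard and the overall mean log-hazard. A single
#' fit identifies only `L - 1` of the `L` contrasts, so the model is fitted
#' twice with different omitted levels and the contrast tables merged; the
#' two fits are the same model in different parametrizations, hence the
#' metagene term and the likelihood-ratio statistic are identical between
#' them.
#'
#' @param data survival dataset from [as_survival_dataset].
#' @param metagene numeric covariate, named by sample ID or aligned with
#'   `data` rows.
#' @param subtype factor/character subtype per sample (defaults to the
#'   dataset's `subtype` column); empty levels are dropped with a warning.
#' @param standardize scale the metagene to unit variance (default `TRUE`).
#' @return a `cox_fit` whose `terms` hold the metagene row plus one
#'   deviation contrast per subtype level; `lrt` is the model
#'   likelihood-ratio test.
#' @export
cox_multivariate_deviation <- function(data, metagene, subtype = data$subtype,
                                       standardize = TRUE) {
  if (!is.null(names(metagene))) {
    idx <- match(data$sample_id, names(metagene))
    assert_that(!anyNA(idx), "metagene values missing for some samples")
    metagene <- metagene[idx]
  }
  assert_that(length(metagene) == nrow(data), "metagene length mismatch")
  assert_that(all(is.finite(metagene)), "non-finite metagene")
  assert_that(sum(data$event) >= 2, "need at least 2 events")
  subtype <- as.character(subtype)
  assert_that(length(subtype) == nrow(data) && !anyNA(subtype) &&
              all(subtype != "UNKNOWN"),
              "every sample needs a known subtype label (impute first)")
  lev <- intersect(GBM_SUBTYPES, unique(subtype))
  if (length(lev) < length(unique(subtype)))
    lev <- unique(c(lev, setdiff(unique(subtype), lev)))
  missing_lev <- setdiff(GBM_SUBTYPES, lev)
  if (length(missing_lev) > 0)
    warning("dropping empty subtype level(s): ",
            paste(missing_lev, collapse = ", "))
  assert_that(length(lev) >= 2, "need at least 2 subtype levels")
  x <- as.numeric(metagene)
  if (standardize) x <- x / stats::sd(x)

  fit_once <- function(level_order) {
    df_fit <- data.frame(time = data$time, event = as.integer(data$event),
                         metagene = x,
                         subtype = factor(subtype, levels = level_order))
    stats::contrasts(df_fit$subtype) <- stats::contr.sum(length(level_order))
    fit <- fit_coxph(survival::Surv(time, event) ~ metagene + subtype, df_fit)
    list(fit = fit, levels = level_order)
  }

  L <- length(lev)
  f1 <- fit_once(lev)
  f2 <- fit_once(c(lev[L], lev[-L])) # rotate so the omitted level gets a row
  s1 <- summary(f1$fit); s2 <- summary(f2$fit)
  co1 <- s1$coefficients; co2 <- s2$coefficients
  ## contr.sum rows 2..L map to the first L-1 levels of each ordering
  rows <- rbind(co1[1, , drop = FALSE],             # metagene
                co1[1 + seq_len(L - 1), , drop = FALSE], # lev[1..L-1]
                co2[2, , drop = FALSE])             # lev[L] (first in f2)
  terms <- data.frame(term = c("metagene", paste0("subtype:", lev)),
                      coef = rows[, "coef"], se = rows[, "se(coef)"],
                      stringsAsFactors = FALSE)
  terms$hr <- exp(terms$coef)
  terms$ci_lo <- exp(terms$coef - 1.96 * terms$se)
  terms$ci_hi <- exp(terms$coef + 1.96 * terms$se)
  terms$p <- 2 * stats::pnorm(-abs(terms$coef / terms$se))
  rownames(terms) <- NULL
  lrt <- list(stat = unname(s1$logtest["test"]),
              df = unname(s1$logtest["df"]),
              p = unname(s1$logtest["pvalue"]))
  structure(list(terms = terms, lrt = lrt, n = nrow(data),
                 n_events = sum(data$event)),
            class = "cox_fit")
}

fit_coxph <- function(formula, data) {
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w)))
        stop("Cox fit did not converge: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("Cox fit produced undefined coefficients (singular design)",
         call. = FALSE)
  fit
}

make_cox_fit <- function(fit, term_names = NULL) {
  s <- summary(fit)
  co <- s$coefficients
  terms <- data.frame(term = term_names %||% rownames(co),
                      coef = co[, "coef"], se = co[, "se(coef)"],
                      stringsAsFactors = FALSE)
  terms$hr <- exp(terms$coef)
  terms$ci_lo <- exp(terms$coef - 1.96 * terms$se)
  terms$ci_hi <- exp(terms$coef + 1.96 * terms$se)
  terms$p <- 2 * stats::pnorm(-abs(terms$coef / terms$se))
  rownames(terms) <- NULL
  structure(list(terms = terms,
                 lrt = list(stat = unname(s$logtest["test"]),
                            df = unname(s$logtest["df"]),
                            p = unname(s$logtest["pvalue"])),
                 n = s$n, n_events = s$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d\n", x$n, x$n_events))
  df <- x$terms
  df$hr_ci <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$ci_lo, df$ci_hi)
  print(df[, c("term", "coef", "se", "hr_ci", "p")], row.names = FALSE,
        digits = 3)
  cat(sprintf("Likelihood ratio test = %.3g, df = %d, P = %.4g\n",
              x$lrt$stat, x$lrt$df, x$lrt$p))
  invisible(x)
}
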