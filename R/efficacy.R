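#' Per-patient lesion assessment
#'
#' Baseline and follow-up sums of target-lesion long diameters (mm) plus the
#' flags RECIST classification needs.
#'
#' @param baseline_mm baseline sum of target-lesion long diameters (> 0).
#' @param followup_mm follow-up sum (>= 0).
#' @param undetectable TRUE when all target lesions have disappeared
#'   (implies \code{followup_mm = 0}).
#' @param new_lesion TRUE when a new lesion appeared.
#' @param id optional patient id.
#' @export
lesion_assessment <- function(baseline_mm, followup_mm, undetectable = FALSE,
                              new_lesion = FALSE, id = NA) {
  if (baseline_mm <= 0) stop("baseline diameter sum must be positive")
  if (followup_mm < 0) stop("follow-up diameter sum must be non-negative")
  if (undetectable && followup_mm != 0)
    stop("undetectable lesions imply a zero follow-up sum")
  structure(list(id = id, baseline_mm = baseline_mm,
                 followup_mm = followup_mm, undetectable = undetectable,
                 new_lesion = new_lesion),
            class = "lesion_assessment")
}

#' RECIST response category of one assessment
#'
#' Precedence CR, PD, PR, SD: complete remission when all target lesions are
#' undetectable with the required duration; progression when a new lesion
#' appeared or the diameter sum increased by at least 20%; partial remission
#' when the sum shrank by more than 30%; stable disease otherwise.
#'
#' The PR boundary is strict (a shrink of exactly 30% is SD) and the PD
#' boundary inclusive (an increase of exactly 20% is PD), following the
#' criteria wording used here rather than the usual ">= 30%" RECIST cut;
#' \code{dialect = "standard"} switches PR to the inclusive boundary.
#'
#' @param a a [lesion_assessment()].
#' @param duration_ok remission duration of at least 4 weeks confirmed.
#' @param dialect \code{"paper"} (default, strict PR) or \code{"standard"}.
#' @return factor level among CR, PR, SD, PD.
#' @examples
#' classify_response(lesion_assessment(100, 69.9))   # PR
#' classify_response(lesion_assessment(100, 70.0))   # SD
#' classify_response(lesion_assessment(100, 120.0))  # PD
#' @export
classify_response <- function(a, duration_ok = TRUE,
                              dialect = c("paper", "standard")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(a, "lesion_assessment"))
  cat <- if (a$undetectable && duration_ok) {
    "CR"
  } else if (a$new_lesion || a$followup_mm >= 1.20 * a$baseline_mm) {
    "PD"
  } else if (if (dialect == "paper") a$followup_mm < 0.70 * a$baseline_mm
             else a$followup_mm <= 0.70 * a$baseline_mm) {
    "PR"
  } else {
    "SD"
  }
  factor(cat, levels = c("CR", "PR", "SD", "PD"))
}

#' Objective response and disease control rates
#'
#' ORR = 100 (CR + PR) / total; DCR = 100 (CR + PR + SD) / total, both
#' reported to 0.1%.
#'
#' @param cr,pr,sd_,pd category counts (the stable-disease argument carries
#'   a trailing underscore to avoid masking [base::sd]).
#' @param group optional group label.
#' @return object of class \code{"efficacy_summary"}: list with the counts,
#'   \code{n}, \code{orr}, \code{dcr}, \code{group}.
#' @examples
#' efficacy_rates(0, 4, 11, 5)   # ORR 20.0, DCR 75.0
#' efficacy_rates(0, 4, 14, 2)   # ORR 20.0, DCR 90.0
#' @export
efficacy_rates <- function(cr, pr, sd_, pd, group = NA_character_) {
  counts <- c(CR = cr, PR = pr, SD = sd_, PD = pd)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("total case count is zero")
  structure(list(counts = counts, n = n,
                 orr = round(100 * (cr + pr) / n, 1),
                 dcr = round(100 * (cr + pr + sd_) / n, 1),
                 group = group),
            class = "efficacy_summary")
}

#' @export
print.efficacy_summary <- function(x, ...) {
  cat(sprintf("%s n = %d | CR %d, PR %d, SD %d, PD %d | ORR %.1f%%, DCR %.1f%%\n",
              if (is.na(x$group)) "" else paste0(x$group, ":"),
              x$n, x$counts["CR"], x$counts["PR"], x$counts["SD"],
              x$counts["PD"], x$orr, x$dcr))
  invisible(x)
}

#' Kaplan-Meier progression-free-survival curve
#'
#' Product-limit estimate over the distinct event times (censored records
#' reduce the risk set without contributing an event factor), with the
#' median read as the earliest time at which the estimate drops to 0.5 or
#' below; if the curve never crosses 0.5 the median is undefined and
#' flagged.
#'
#' @param records data.frame with columns \code{time} (months, >= 0) and
#'   \code{event} (1 = progression, 0 = censored).
#' @return object of class \code{"km_curve"}: list with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{median} (months or
#'   \code{NA}), \code{median_defined}.
#' @examples
#' km_curve(data.frame(time = 1:4, event = 1))$median   # 2
#' @export
km_curve <- function(records) {
  if (nrow(records) < 1L) stop("at least one record is required")
  if (any(records$time < 0)) stop("negative survival time")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = records$time, event = records$event))
  # earliest time with S(t) <= 0.5 (survfit interpolates flat 0.5 stretches)
  below <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(below)) fit$time[min(below)] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = med, median_defined = !is.na(med)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median %s months\n",
              length(x$time),
              if (x$median_defined) sprintf("%.2f", x$median)
              else "undefined (curve stays above 0.5)"))
  invisible(x)
}

#' Chi-square comparison of two response rates
#'
#' Pearson chi-square on the 2x2 successes/failures table of two groups,
#' optional Yates correction; df = 1.
#'
#' @param success1,total1,success2,total2 counts per group.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chi2_compare <- function(success1, total1, success2, total2,
                         correct = FALSE) {
  if (total1 <= 0 || total2 <= 0) stop("group totals must be positive")
  tab <- rbind(c(success1, total1 - success1),
               c(success2, total2 - success2))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate margin in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
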