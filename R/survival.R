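# Score-based cohort stratification, Kaplan-Meier estimation and log-rank
# testing (product-limit and log-rank delegated to the survival package),
# plus score-vs-signature correlation panels.

#' Stratify a cohort by signature score
#'
#' Tertile scheme: patients are sorted by score (ties, including the
#' all-equal degenerate case, broken by patient id), the lowest
#' ceiling(n/3) form the low group and the highest ceiling(n/3) the high
#' group, the remainder is mid — so 277 patients split 93 / 91 / 93, with
#' remainder patients going to the outer groups. Median scheme: lower half
#' low, upper half high, no mid.
#'
#' @param scores a `score_vector` (or named numeric) of per-patient scores.
#' @param clinical data.frame with patient_id, time_months, event (0/1).
#' @param scheme "tertiles" (default) or "median".
#' @return a `cohort_score` data.frame: patient_id, score, time_months,
#'   event, group (factor low/mid/high).
#' @export
stratify <- function(scores, clinical, scheme = c("tertiles", "median")) {
  scheme <- match.arg(scheme)
  s <- if (inherits(scores, "score_vector")) scores$score else scores
  if (is.null(names(s))) stop("scores must be named by patient id")
  unmatched <- c(setdiff(names(s), clinical$patient_id),
                 setdiff(clinical$patient_id, names(s)))
  if (length(unmatched) > 0)
    stop("unmatched patient ids: ",
         paste(utils::head(unmatched, 10), collapse = ", "),
         if (length(unmatched) > 10)
           sprintf(" ... (%d total)", length(unmatched)))
  if (any(clinical$time_months < 0)) stop("negative survival times")
  n <- length(s)
  if (length(unique(s)) == 1)
    warning("all scores equal; groups assigned by patient-id order")
  ord <- order(s, names(s), method = "radix")
  group <- rep("mid", n)
  if (scheme == "tertiles") {
    n_out <- ceiling(n / 3)
    group[ord[seq_len(n_out)]] <- "low"
    group[ord[seq(n - n_out + 1, n)]] <- "high"
  } else {
    n_low <- floor(n / 2)
    group[ord[seq_len(n_low)]] <- "low"
    group[ord[seq(n_low + 1, n)]] <- "high"
  }
  m <- match(names(s), clinical$patient_id)
  out <- data.frame(patient_id = names(s), score = unname(s),
                    time_months = clinical$time_months[m],
                    event = as.integer(clinical$event[m]),
                    group = factor(group, levels = c("low", "mid", "high")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cohort_score", "data.frame")
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (via [survival::survfit()]); censored subjects
#' leave the risk set without a step.
#'
#' @param time nonnegative times (months).
#' @param event event indicators (1 = event, 0 = censored).
#' @return step-function data.frame: time, n_risk, n_event, n_censor, surv.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one subject")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-vs-expected log-rank (hypergeometric variance, no
#' continuity correction; via [survival::survdiff()]), chi-square with one
#' degree of freedom. With no events in either group the test is undefined
#' and (chi2 = 0, p = 1) is returned with a warning.
#'
#' @param group_a,group_b data.frames with columns `time_months` (or
#'   `time`) and `event`.
#' @return list with `chi2`, `p`, `n` (per-group sizes), `events`.
#' @export
logrank <- function(group_a, group_b) {
  get_col <- function(d, main, alt) if (!is.null(d[[main]])) d[[main]] else d[[alt]]
  ta <- get_col(group_a, "time_months", "time")
  tb <- get_col(group_b, "time_months", "time")
  if (length(ta) == 0 || length(tb) == 0) stop("both groups must be nonempty")
  time <- c(ta, tb)
  event <- c(group_a$event, group_b$event)
  grp <- factor(rep(c("A", "B"), c(length(ta), length(tb))))
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chi2 = 0, p = 1, n = table(grp),
                events = c(A = 0, B = 0)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = sd$n, events = sd$obs)
}

#' Correlation panel of a score against companion signature scores
#'
#' Pairwise correlation (Spearman by default, as used for score-vs-score
#' panels) of the main score against each companion score over the shared
#' patients.
#'
#' @param score a `score_vector` or named numeric (the main score).
#' @param others named list of `score_vector`s or named numerics.
#' @param method "spearman" (default) or "pearson".
#' @return data.frame: name, r, p, n_shared.
#' @export
score_correlation_panel <- function(score, others,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  s <- if (inherits(score, "score_vector")) score$score else score
  rows <- lapply(names(others), function(nm) {
    o <- others[[nm]]
    if (inherits(o, "score_vector")) o <- o$score
    shared <- intersect(names(s), names(o))
    if (length(shared) < 3)
      stop("fewer than 3 shared patients with '", nm, "'")
    ct <- suppressWarnings(
      stats::cor.test(s[shared], o[shared], method = method))
    data.frame(name = nm, r = unname(ct$estimate), p = ct$p.value,
               n_shared = length(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
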