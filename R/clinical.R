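#' Kaplan-Meier product-limit survival estimate
#'
#' Wraps [survival::survfit()] for a single group: the estimate steps at
#' event times with `S(t) = prod(1 - d_i / n_i)`; censored observations
#' reduce the risk set only. Ties between events and censorings at the same
#' time are handled with events first (standard convention).
#'
#' @param time positive survival times (months).
#' @param event 1 = death observed, 0 = right-censored.
#' @return data frame of class `survival_curve` with one row per event time:
#'   `time`, `n_risk`, `n_event`, `survival`; the full step table (including
#'   censoring times) is in `attr(, "full")`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stopf("no records")
  if (any(!is.finite(time) | time <= 0)) stopf("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  full <- data.frame(time = fit$time, n_risk = fit$n.risk,
                     n_event = fit$n.event, n_censor = fit$n.censor,
                     survival = fit$surv)
  curve <- full[full$n_event > 0, c("time", "n_risk", "n_event", "survival")]
  rownames(curve) <- NULL
  structure(curve, full = full, n = length(time),
            class = c("survival_curve", "data.frame"))
}

#' Log-rank comparison of survival between groups
#'
#' Standard O-E log-rank statistic via [survival::survdiff()],
#' chi-squared with `groups - 1` degrees of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group group label per record (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stopf("need >= 2 groups")
  if (any(table(group) == 0)) stopf("empty group")
  if (sum(event) < 1) stopf("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = setNames(as.vector(sd$obs), names(sd$n)),
       expected = setNames(as.vector(sd$exp), names(sd$n)))
}

#' Mutation enrichment per expression quadrant
#'
#' For each quadrant builds the 2x2 table (in-quadrant vs rest) x (mutated
#' vs not) and scores enrichment with a one-sided Fisher's exact test
#' (alternative: more mutations inside the quadrant than expected).
#' Mutation labels other than the designated mutated levels are collapsed to
#' wild type when `collapse_other` is set, reflecting a targeted-detection
#' clinical scenario; samples with unknown status are dropped with a warning.
#'
#' @param quadrants data frame from [assign_quadrants()] (`sample`,
#'   `quadrant`).
#' @param mutation named character vector sample -> status (`wild_type`,
#'   `L265P`, `other`, `unknown`).
#' @param mutated_levels status values counted as mutated (default
#'   `"L265P"`; use `c("L265P", "other")` for "any mutation").
#' @param collapse_other treat `other` as wild type when it is not in
#'   `mutated_levels` (default TRUE).
#' @return data frame per quadrant: `quadrant`, `mutated_in`, `n_in`,
#'   `mutated_out`, `n_out`, `p_value`, `odds_ratio`.
#' @export
mutation_association <- function(quadrants, mutation,
                                 mutated_levels = "L265P",
                                 collapse_other = TRUE) {
  status <- mutation[quadrants$sample]
  if (any(is.na(status))) stopf("mutation status missing for some samples")
  if (collapse_other)
    status[status == "other" & !"other" %in% mutated_levels] <- "wild_type"
  unknown <- status == "unknown"
  if (any(unknown)) {
    warnf("%d sample(s) with unknown mutation status dropped", sum(unknown))
    quadrants <- quadrants[!unknown, ]
    status <- status[!unknown]
  }
  bad <- setdiff(unique(status), c("wild_type", mutated_levels))
  if (length(bad)) stopf("unhandled mutation status: %s (no collapse rule)",
                         paste(bad, collapse = ", "))
  mut <- status %in% mutated_levels
  rows <- lapply(sort(unique(quadrants$quadrant)), function(q) {
    inq <- quadrants$quadrant == q
    tab <- matrix(c(sum(inq & mut), sum(inq & !mut),
                    sum(!inq & mut), sum(!inq & !mut)), 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(quadrant = q, mutated_in = tab[1, 1], n_in = sum(tab[1, ]),
               mutated_out = tab[2, 1], n_out = sum(tab[2, ]),
               p_value = ft$p.value, odds_ratio = unname(ft$estimate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
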