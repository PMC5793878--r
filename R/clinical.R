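#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Genes are ordered by expression (descending; ties broken by rank with
#' average tie ranks feeding the weights).  Walking down the list, the
#' weighted in-set cumulative distribution
#' \eqn{P_{in}(i) = \sum_{g \in set, pos \le i} \rho_g^\alpha /
#' \sum_{g \in set} \rho_g^\alpha} (with \eqn{\rho_g} the expression rank,
#' highest expression = largest rank) is compared against the unweighted
#' out-of-set ECDF, and the enrichment score is the sum of their differences
#' over all positions.  `alpha = 0` reduces to the unweighted rank statistic.
#'
#' @param expr named numeric vector of one sample's expression values.
#' @param gene_set character vector of at least two distinct gene ids;
#'   must intersect the measured genes.
#' @param alpha rank weighting exponent (default 0.25).
#' @return enrichment score (finite scalar).
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2L) stop("gene set must have >= 2 distinct members")
  if (is.null(names(expr))) stop("expression vector must be named")
  hits <- names(expr) %in% gene_set
  if (!any(hits)) stop("gene set has no member among measured genes")
  if (all(hits)) stop("gene set covers every measured gene; no background")
  rho <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr))
  h <- hits[ord]
  w <- ifelse(h, rho[ord]^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!h) / sum(!h)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample and gene set
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param gene_sets named list of gene-id vectors.
#' @param alpha rank weighting exponent.
#' @return samples x sets matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25) {
  out <- matrix(NA_real_, ncol(expr), length(gene_sets),
                dimnames = list(colnames(expr), names(gene_sets)))
  for (j in seq_len(ncol(expr))) {
    v <- setNames(expr[, j], rownames(expr))
    for (s in names(gene_sets)) {
      out[j, s] <- ssgsea_score(v, gene_sets[[s]], alpha = alpha)
    }
  }
  out
}

#' Stratify samples by median split of two gene-set scores
#'
#' Each axis is split at its cohort median (scores at or below the median
#' are "low"), giving a 2x2 stratification named
#' `<set1><low/high>-<set2><low/high>`.  Custom split points can be given
#' (e.g. a reference-group mean).
#'
#' @param scores two-column matrix or data frame of per-sample scores with
#'   column names; at least two samples.
#' @param split optional length-2 numeric split points per axis (default:
#'   cohort medians).
#' @return factor of stratum labels, one per sample, with all four levels.
#' @export
stratify_samples <- function(scores, split = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("exactly two score columns required")
  if (nrow(scores) < 2L) stop("at least two samples required")
  nm <- colnames(scores)
  if (is.null(nm)) nm <- c("set1", "set2")
  if (is.null(split)) split <- apply(scores, 2, median)
  side <- matrix("high", nrow(scores), 2L)
  for (j in 1:2) {
    if (length(unique(scores[, j])) == 1L) {
      stop(sprintf("all samples have equal '%s' score; no split possible",
                   nm[j]))
    }
    side[scores[, j] <= split[j], j] <- "low"
  }
  lv <- as.vector(outer(c("low", "high"), c("low", "high"),
                        function(a, b) paste0(nm[1L], a, "-", nm[2L], b)))
  factor(paste0(nm[1L], side[, 1L], "-", nm[2L], side[, 2L]), levels = lv)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Thin wrapper over [survival::survfit()]: censored observations only
#' shrink the risk set.  The returned object carries the step function
#' \eqn{\hat S(t)} (right-continuous, `S(0) = 1`).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return object of class `km_fit`: list with `time`, `n_risk`,
#'   `n_event`, `surv` and `step`, a function evaluating \eqn{\hat S(t)}.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  if (length(times) != length(events)) stop("times/events length mismatch")
  fit <- survfit(Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv,
                 step = stepfun(fit$time, c(1, fit$surv), right = FALSE)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d time point(s), %d event(s)\n",
              length(x$time), sum(x$n_event)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the event
#' experience of two groups (via [survival::survdiff()]).
#'
#' @param time1,event1 follow-up and event indicator of group 1.
#' @param time2,event2 follow-up and event indicator of group 2.
#' @return list with `statistic` and `p_value`.
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (length(time1) == 0L || length(time2) == 0L) stop("empty group")
  if (any(c(time1, time2) < 0)) stop("negative survival time")
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp <- rep(c(1L, 2L), c(length(time1), length(time2)))
  if (sum(event) == 0L) return(list(statistic = 0, p_value = 1))
  sd <- survdiff(Surv(time, event) ~ grp)
  stat <- sd$chisq
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
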