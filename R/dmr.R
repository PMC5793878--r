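check_sorted <- function(chrom, pos, what = "input") {
  o <- order(chrom, pos)
  if (!identical(o, seq_along(pos))) {
    stop(sprintf("%s must be sorted by (chrom, pos)", what))
  }
  invisible(TRUE)
}

#' Filter site-level results to differentially methylated CpGs
#'
#' Applies the three site-level filters: RSLRT p value below `p_cutoff`
#' (strict), absolute methylation difference above `delta_min` (strict),
#' and weighted coverage of at least `min_wcov`.  The direction is the sign
#' of delta (`hyper` = gain in the second scanned group).
#'
#' @param results sorted output of [site_scan()].
#' @param p_cutoff,delta_min,min_wcov filter thresholds
#'   (defaults 0.05, 0.10, 10).
#' @return filtered `data.frame` with an added `direction` column.
#' @export
call_dm_sites <- function(results, p_cutoff = 0.05, delta_min = 0.10,
                          min_wcov = 10) {
  check_sorted(results$chrom, results$pos, "site results")
  keep <- results$p_value < p_cutoff &
    abs(results$delta) > delta_min &
    results$weighted_coverage >= min_wcov
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Merge differentially methylated CpGs into candidate regions
#'
#' Same-direction DM CpGs on the same chromosome are chained while the gap
#' between successive CpGs is at most `max_gap` (default 5,000 bp).  Hyper-
#' and hypo-methylated CpGs never share a region.  The region span runs from
#' the first member CpG to one past the last (0-based half-open).  Singleton
#' chains are kept as candidates; the "at least 2 DM CpGs" rule is applied
#' later at the region-testing stage.
#'
#' @param sites output of [call_dm_sites()], sorted by `(chrom, pos)`.
#' @param max_gap maximum merge distance in bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `direction`,
#'   `n_sites`, and a `members` list-column of member CpG positions.
#' @export
merge_dm_sites <- function(sites, max_gap = 5000) {
  check_sorted(sites$chrom, sites$pos, "DM sites")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_sites = integer(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(sites) == 0L) return(empty)
  if (is.null(sites$direction)) stop("sites lack a direction column")
  out <- list()
  for (dir in c("hyper", "hypo")) {
    s <- sites[sites$direction == dir, , drop = FALSE]
    if (nrow(s) == 0L) next
    new_chain <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)] |
                     diff(s$pos) > max_gap)
    id <- cumsum(new_chain)
    first <- tapply(seq_len(nrow(s)), id, min)
    last <- tapply(seq_len(nrow(s)), id, max)
    reg <- data.frame(chrom = s$chrom[first], start = s$pos[first],
                      end = s$pos[last] + 1L, direction = dir,
                      n_sites = as.integer(table(id)),
                      stringsAsFactors = FALSE)
    reg$members <- unname(split(s$pos, id))
    out[[dir]] <- reg
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-level RSLRT with Benjamini-Hochberg control and effect filters
#'
#' For every candidate region the member CpG counts are summed per replicate
#' (members only by default; set `all_cpgs = TRUE` to aggregate every CpG in
#' the span) and the two groups are compared with [rslrt_test()].  P values
#' are BH-adjusted jointly across all candidate regions of both directions.
#' A region passes when `p_adj < padj_cutoff` and (|delta| > `delta_min` or
#' fold change > `fc_min`) and it contains at least `min_dm_cpgs` DM CpGs.
#' The fold change of proportions is `(max(p1,p2)+eps)/(min(p1,p2)+eps)`
#' with a zero guard `eps` of one percentage point.
#'
#' @param candidates output of [merge_dm_sites()].
#' @param mat the `CpGCountMatrix` the sites came from.
#' @param group_a,group_b group labels as in [site_scan()].
#' @param rho optional dispersion (pass the value used in the site scan).
#' @param padj_cutoff,delta_min,fc_min,min_dm_cpgs,eps filter parameters
#'   (defaults 0.01, 0.30, 5, 2, 0.01).
#' @param all_cpgs aggregate all CpGs in the span instead of members only.
#' @return `data.frame` of all candidates with region statistics,
#'   `fold_change`, `n_dm_cpgs`, `p_adj` and logical `passes`.
#' @export
test_regions <- function(candidates, mat, group_a, group_b, rho = NULL,
                         padj_cutoff = 0.01, delta_min = 0.30, fc_min = 5,
                         min_dm_cpgs = 2, eps = 0.01, all_cpgs = FALSE) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    for (col in c("p1", "p2", "delta", "G2", "d1", "d2", "G2_adj",
                  "p_value", "weighted_coverage", "fold_change", "p_adj")) {
      out[[col]] <- numeric()
    }
    out$n_dm_cpgs <- integer()
    out$passes <- logical()
    return(out)
  }
  site_key <- paste(mat$chrom, mat$pos)
  ca <- group_columns(mat, group_a)
  cb <- group_columns(mat, group_b)
  nreg <- nrow(candidates)
  idx <- vector("list", nreg)
  for (i in seq_len(nreg)) {
    if (all_cpgs) {
      j <- which(mat$chrom == candidates$chrom[i] &
                   mat$pos >= candidates$start[i] &
                   mat$pos < candidates$end[i])
    } else {
      j <- match(paste(candidates$chrom[i], candidates$members[[i]]), site_key)
    }
    if (length(j) == 0L || anyNA(j)) {
      stop(sprintf("region %s:%d-%d has no member counts in the matrix",
                   candidates$chrom[i], candidates$start[i],
                   candidates$end[i]))
    }
    idx[[i]] <- j
  }
  grp <- rep(seq_len(nreg), lengths(idx))
  rows <- unlist(idx)
  agg <- function(x) rowsum(x[rows, , drop = FALSE], grp, reorder = TRUE)
  res <- rslrt_engine(agg(mat$meth[, ca, drop = FALSE]),
                      agg(mat$total[, ca, drop = FALSE]),
                      agg(mat$meth[, cb, drop = FALSE]),
                      agg(mat$total[, cb, drop = FALSE]), rho = rho)
  out <- cbind(candidates, res)
  out$fold_change <- (pmax(out$p1, out$p2) + eps) / (pmin(out$p1, out$p2) + eps)
  out$n_dm_cpgs <- candidates$n_sites
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$passes <- out$p_adj < padj_cutoff &
    (abs(out$delta) > delta_min | out$fold_change > fc_min) &
    out$n_dm_cpgs >= min_dm_cpgs
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions between two groups
#'
#' End-to-end composition: site-level RSLRT scan, site filters, merging of
#' DM CpGs within 5 kb into same-direction candidate regions, region-level
#' RSLRT with BH adjustment and effect-size filters.  Passing regions are
#' split into hyper- (gain in `group_b`) and hypo-methylated DMRs and given
#' ids `hyper_001`, `hypo_001`, ...
#'
#' @param mat a `CpGCountMatrix`.
#' @param group_a,group_b control and case group labels.
#' @param site_p,site_delta,site_wcov site-level thresholds
#'   (defaults 0.05, 0.10, 10).
#' @param max_gap merge distance (default 5,000 bp).
#' @param padj_cutoff,region_delta,region_fc,min_dm_cpgs,eps region-level
#'   thresholds (defaults 0.01, 0.30, 5, 2, 0.01).
#' @param moderate use the genome-wide moderated design effect
#'   (default `TRUE`; see [site_scan()]).
#' @param all_cpgs region aggregation mode (see [test_regions()]).
#' @return object of class `dmr_result`: list with `hyper` and `hypo`
#'   (passing DMRs), `regions` (all tested candidates), `sites` (DM sites),
#'   `audit` (named stage counts) and `rho`.
#' @export
call_dmrs <- function(mat, group_a, group_b,
                      site_p = 0.05, site_delta = 0.10, site_wcov = 10,
                      max_gap = 5000, padj_cutoff = 0.01,
                      region_delta = 0.30, region_fc = 5, min_dm_cpgs = 2,
                      eps = 0.01, moderate = TRUE, all_cpgs = FALSE) {
  scan <- site_scan(mat, group_a, group_b, moderate = moderate)
  rho <- attr(scan, "rho")
  sites <- call_dm_sites(scan, p_cutoff = site_p, delta_min = site_delta,
                         min_wcov = site_wcov)
  cands <- merge_dm_sites(sites, max_gap = max_gap)
  regions <- test_regions(cands, mat, group_a, group_b, rho = rho,
                          padj_cutoff = padj_cutoff,
                          delta_min = region_delta, fc_min = region_fc,
                          min_dm_cpgs = min_dm_cpgs, eps = eps,
                          all_cpgs = all_cpgs)
  pass <- regions[regions$passes, , drop = FALSE]
  split_dir <- function(dir) {
    d <- pass[pass$direction == dir, , drop = FALSE]
    if (nrow(d) > 0L) {
      d$dmr_id <- sprintf("%s_%03d", dir, seq_len(nrow(d)))
    } else {
      d$dmr_id <- character()
    }
    rownames(d) <- NULL
    d
  }
  hyper <- split_dir("hyper")
  hypo <- split_dir("hypo")
  audit <- c(n_sites_tested = nrow(scan),
             n_sites_skipped = attr(scan, "skipped"),
             n_dm_sites = nrow(sites),
             n_candidate_regions = nrow(cands),
             n_passing = nrow(pass),
             n_hyper = nrow(hyper),
             n_hypo = nrow(hypo))
  structure(list(hyper = hyper, hypo = hypo, regions = regions,
                 sites = sites, audit = audit, rho = rho),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("DMR call:\n")
  for (nm in names(x$audit)) cat(sprintf("  %-20s %d\n", nm, x$audit[[nm]]))
  invisible(x)
}
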