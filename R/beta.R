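#' Distance-decayed regulatory potential of DMRs near a gene TSS
#'
#' For each gene, sums `exp(-(0.5 + 4 * d/scale))` over all DMRs whose
#' center lies within `window` bp of the TSS, where `d` is the center-to-TSS
#' distance.  With the defaults (window = scale = 100 kb) a DMR centered on
#' the TSS contributes `exp(-0.5)` and one at the window edge `exp(-4.5)`.
#' Genes with no DMR in range score 0.
#'
#' @param genes gene models with `gene_id`, `chrom`, `tss`.
#' @param dmrs `data.frame` with `chrom`, `start`, `end`.
#' @param window inclusion window around the TSS in bp.
#' @param scale distance normalisation in bp (defaults to `window`).
#' @return numeric vector of scores named by `gene_id`.
#' @export
regulatory_potential <- function(genes, dmrs, window = 1e5, scale = window) {
  center <- floor((dmrs$start + dmrs$end) / 2)
  s <- setNames(numeric(nrow(genes)), genes$gene_id)
  for (ch in unique(genes$chrom)) {
    ci <- which(dmrs$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(ci) == 0L || length(gi) == 0L) next
    cc <- center[ci]
    for (g in gi) {
      d <- abs(cc - genes$tss[g])
      d <- d[d <= window]
      if (length(d)) s[g] <- sum(exp(-(0.5 + 4 * d / scale)))
    }
  }
  s
}

## one-sided two-sample KS: D+ = sup(F_x - F_y); exact permutation p for
## small samples, asymptotic exp(-2 D^2 nm/(n+m)) otherwise.  Handles ties.
ks_one_sided <- function(x, y, exact_limit = 20000) {
  nx <- length(x); ny <- length(y)
  dplus <- function(xv, yv) {
    pts <- sort(unique(c(xv, yv)))
    max(vapply(pts, function(t) mean(xv <= t) - mean(yv <= t), 0))
  }
  D <- dplus(x, y)
  if (choose(nx + ny, nx) <= exact_limit) {
    pool <- c(x, y)
    combs <- combn(nx + ny, nx)
    perm <- apply(combs, 2, function(i) dplus(pool[i], pool[-i]))
    p <- mean(perm >= D - 1e-12)
  } else {
    p <- min(1, exp(-2 * D^2 * nx * ny / (nx + ny)))
  }
  list(D = D, p = p, n_x = nx, n_y = ny)
}

#' Activating/repressive function test of DMRs (KS on potential ranks)
#'
#' Genes are ranked by regulatory potential `S` (descending, average ties).
#' The rank distributions of up- and downregulated genes are each compared
#' against the non-differential background with a one-sided
#' Kolmogorov-Smirnov test asking whether the class is shifted toward
#' better (smaller) ranks, i.e. higher potential.  For small samples the p
#' value is an exact permutation tail; otherwise the one-sided asymptotic
#' approximation is used.
#'
#' @param genes `data.frame` with columns `gene_id`, `S` (regulatory
#'   potential) and `de_class` in `{"UP","DOWN","NON"}`.
#' @return list with `UP` and `DOWN` (each `D`, `p`, class size) and
#'   `curves`, a table of cumulative rank-coverage per class for plotting.
#' @export
beta_function_test <- function(genes) {
  if (!any(genes$de_class == "NON")) stop("empty NON background class")
  r <- rank(-genes$S, ties.method = "average")
  res <- list()
  for (cl in c("UP", "DOWN")) {
    x <- r[genes$de_class == cl]
    if (length(x) == 0L) {
      res[[cl]] <- list(D = NA_real_, p = NA_real_, n_x = 0L,
                        n_y = sum(genes$de_class == "NON"))
      next
    }
    res[[cl]] <- ks_one_sided(x, r[genes$de_class == "NON"])
  }
  grid <- sort(unique(r))
  curves <- data.frame(rank = grid)
  for (cl in c("UP", "DOWN", "NON")) {
    x <- r[genes$de_class == cl]
    curves[[cl]] <- if (length(x)) {
      vapply(grid, function(t) mean(x <= t), 0)
    } else NA_real_
  }
  c(res, list(curves = curves))
}

#' Rank-product target genes from potential and expression evidence
#'
#' Over the `N` supplied genes, ranks are assigned ascending by decreasing
#' evidence: `rank_S` by regulatory potential (highest `S` = rank 1),
#' `rank_E` by differential-expression p value (smallest = rank 1), ties
#' sharing the mean rank.  The rank product `RP = (rank_S/N) * (rank_E/N)`
#' behaves like a p value; genes with `RP < cutoff` are called targets.
#' By default all genes carrying both evidence dimensions are ranked, so
#' targets need not themselves reach expression significance — strong
#' regulatory potential can rescue a sub-threshold expression trend.
#' `de_only = TRUE` restricts the ranking to UP/DOWN genes.
#'
#' @param genes `data.frame` with `gene_id`, `S` and `pvalue`
#'   (differential-expression p); `de_class` required for `de_only`.
#' @param cutoff rank-product cutoff (default 0.001).
#' @param de_only rank only significantly differentially expressed genes.
#' @return `data.frame` of the N ranked genes with `rank_S`, `rank_E`,
#'   `RP` and `is_target`, ordered by `RP`.
#' @export
rank_product_targets <- function(genes, cutoff = 0.001, de_only = FALSE) {
  de <- if (de_only) {
    genes[genes$de_class %in% c("UP", "DOWN"), , drop = FALSE]
  } else {
    genes
  }
  n <- nrow(de)
  if (n == 0L) stop("no genes to rank")
  de$rank_S <- rank(-de$S, ties.method = "average")
  de$rank_E <- rank(de$pvalue, ties.method = "average")
  de$RP <- (de$rank_S / n) * (de$rank_E / n)
  de$is_target <- de$RP < cutoff
  de <- de[order(de$RP), , drop = FALSE]
  rownames(de) <- NULL
  de
}

#' Per-class distribution of DMRs near genes
#'
#' Scores each gene by the number of DMRs (or their summed regulatory
#' potential) whose center lies within `window` bp of its TSS, and compares
#' the up- and downregulated classes against the non-differential
#' background with a Wilcoxon rank-sum test.
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss`, `de_class`.
#' @param dmrs `data.frame` with `chrom`, `start`, `end`.
#' @param window window in bp (> 0).
#' @param stat `"count"` or `"potential"`.
#' @return list with `scores` (`gene_id`, `de_class`, `score`),
#'   `p_up_vs_non`, `p_down_vs_non`.
#' @export
dmr_gene_enrichment <- function(genes, dmrs, window = 1e5,
                                stat = c("count", "potential")) {
  if (window <= 0) stop("window must be positive")
  stat <- match.arg(stat)
  center <- floor((dmrs$start + dmrs$end) / 2)
  score <- setNames(numeric(nrow(genes)), genes$gene_id)
  for (ch in unique(genes$chrom)) {
    cc <- center[dmrs$chrom == ch]
    gi <- which(genes$chrom == ch)
    if (length(cc) == 0L || length(gi) == 0L) next
    for (g in gi) {
      d <- abs(cc - genes$tss[g])
      d <- d[d <= window]
      score[g] <- if (stat == "count") length(d) else
        sum(exp(-(0.5 + 4 * d / window)))
    }
  }
  cmp <- function(cl) {
    x <- score[genes$de_class == cl]
    y <- score[genes$de_class == "NON"]
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    if (length(unique(c(x, y))) == 1L) return(1)
    suppressWarnings(wilcox.test(x, y)$p.value)
  }
  list(scores = data.frame(gene_id = genes$gene_id,
                           de_class = genes$de_class,
                           score = unname(score),
                           stringsAsFactors = FALSE),
       p_up_vs_non = cmp("UP"), p_down_vs_non = cmp("DOWN"))
}
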