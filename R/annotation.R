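#' Signed distance from each DMR to the nearest gene TSS
#'
#' The distance runs from the DMR midpoint (`floor((start+end)/2)`) to the
#' nearest TSS; it is 0 when the TSS lies inside the DMR.  The sign respects
#' gene strand: positive when the DMR midpoint is downstream of the TSS,
#' negative upstream.  Equidistant TSSs are broken deterministically by
#' gene id.  DMRs on chromosomes without any gene get `NA`; their count is
#' attached as attribute `"n_undefined"`.
#'
#' @param dmrs `data.frame` with `chrom`, `start`, `end`.
#' @param genes gene models as from [read_gene_models()].
#' @return `data.frame` with `chrom`, `start`, `end`, `gene_id`,
#'   `distance`.
#' @export
distance_to_nearest_tss <- function(dmrs, genes) {
  n <- nrow(dmrs)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  for (ch in unique(dmrs$chrom)) {
    gi <- which(genes$chrom == ch)
    di <- which(dmrs$chrom == ch)
    if (length(gi) == 0L) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    for (i in di) {
      d_abs <- abs(g$tss - mid[i])
      best <- order(d_abs, g$gene_id)[1L]
      gene_id[i] <- g$gene_id[best]
      if (g$tss[best] >= dmrs$start[i] && g$tss[best] < dmrs$end[i]) {
        distance[i] <- 0
      } else {
        raw <- mid[i] - g$tss[best]
        distance[i] <- if (g$strand[best] == "+") raw else -raw
      }
    }
  }
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    gene_id = gene_id, distance = distance,
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(distance))
  out
}

#' Generate length- and chromosome-matched random control regions
#'
#' For each requested set, every DMR is re-placed uniformly at random on its
#' own chromosome with its own length, rejecting placements that overlap any
#' DMR.  Deterministic under `seed`.
#'
#' @param dmrs `data.frame` with `chrom`, `start`, `end`.
#' @param genome_sizes named vector of chromosome sizes (bp).
#' @param n_sets number of control sets.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per region.
#' @return list of `n_sets` `data.frame`s with `chrom`, `start`, `end`.
#' @export
generate_matched_controls <- function(dmrs, genome_sizes, n_sets = 10,
                                      seed = 1, max_tries = 1000) {
  if (n_sets == 0L) return(list())
  set.seed(seed)
  lens <- dmrs$end - dmrs$start
  out <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    starts <- integer(nrow(dmrs))
    for (i in seq_len(nrow(dmrs))) {
      ch <- dmrs$chrom[i]
      size <- genome_sizes[[ch]]
      if (is.null(size) || size < lens[i]) {
        stop(sprintf("chromosome %s too short to place a %d bp control",
                     ch, lens[i]))
      }
      dch <- which(dmrs$chrom == ch)
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        s0 <- floor(runif(1, 0, size - lens[i] + 1))
        if (!any(s0 < dmrs$end[dch] & s0 + lens[i] > dmrs$start[dch])) {
          starts[i] <- as.integer(s0)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place control for %s:%d-%d after %d tries",
                     ch, dmrs$start[i], dmrs$end[i], max_tries))
      }
    }
    out[[s]] <- data.frame(chrom = dmrs$chrom, start = starts,
                           end = starts + lens, stringsAsFactors = FALSE)
  }
  out
}

as_granges0 <- function(df) {
  # 0-based half-open -> 1-based inclusive
  GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
}

#' Overlap enrichment of DMRs in an annotation set versus matched controls
#'
#' A region "overlaps" the annotation when they share at least one bp
#' (exact on 0-based half-open coordinates).  The empirical p value is
#' `(1 + #control sets with overlap percentage >= observed) /
#' (1 + #control sets)`; the hypergeometric p value is the upper tail of
#' the observed overlap count when drawing `#DMRs` regions from the
#' universe formed by the DMRs and all control regions.
#'
#' @param dmrs `data.frame` with `chrom`, `start`, `end`.
#' @param annotation `data.frame` with `chrom`, `start`, `end` (may contain
#'   internal overlaps).
#' @param controls list of control sets from [generate_matched_controls()].
#' @return list with `pct_dmrs`, `mean_pct_controls`, `empirical_p`,
#'   `hypergeom_p`, and the underlying counts.
#' @export
overlap_enrichment <- function(dmrs, annotation, controls) {
  if (nrow(annotation) == 0L) stop("empty annotation set")
  if (length(controls) < 1L) stop("at least one control set required")
  ann <- as_granges0(annotation)
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # condition worth a seqlevel warning
  n_ov <- function(df) sum(suppressWarnings(
    countOverlaps(as_granges0(df), ann, minoverlap = 1L)) > 0)
  k_dmr <- n_ov(dmrs)
  pct_dmrs <- 100 * k_dmr / nrow(dmrs)
  k_ctrl <- vapply(controls, n_ov, 0L)
  n_ctrl <- vapply(controls, nrow, 0L)
  pct_ctrl <- 100 * k_ctrl / n_ctrl
  empirical_p <- (1 + sum(pct_ctrl >= pct_dmrs)) / (1 + length(controls))
  N <- nrow(dmrs) + sum(n_ctrl)
  K <- k_dmr + sum(k_ctrl)
  hypergeom_p <- phyper(k_dmr - 1, K, N - K, nrow(dmrs), lower.tail = FALSE)
  list(pct_dmrs = pct_dmrs, mean_pct_controls = mean(pct_ctrl),
       empirical_p = empirical_p, hypergeom_p = hypergeom_p,
       n_overlap = k_dmr, n_dmrs = nrow(dmrs),
       universe = N, annotated_in_universe = K)
}
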