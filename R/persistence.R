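#' Retention index of DMRs in a post-intervention group
#'
#' Pools methylated/total counts over each DMR's member CpGs and all
#' replicates of the three groups, then places the post-intervention level
#' on the control-to-case axis:
#' \deqn{r = (m_{FO} - m_{LF}) / (m_{HF} - m_{LF})}
#' clipped to `[-0.5, 1.5]`.  `r = 1` means the methylation change is fully
#' retained after the intervention, `r = 0` fully reversed.  DMRs where the
#' case and control levels coincide have an undefined index (`NA`, counted
#' in attribute `"n_undefined"`).
#'
#' @param dmrs `data.frame` with `chrom` and a `members` list-column of
#'   member CpG positions (as produced by [call_dmrs()]), plus optionally
#'   `dmr_id` and `direction`.
#' @param mat `CpGCountMatrix` containing all three groups.
#' @param groups character(3): control, case and post-intervention group
#'   labels, in that order.
#' @param clip length-2 clipping range for `r`.
#' @return `data.frame` with `dmr_id`, `direction`, `m_LF`, `m_HF`,
#'   `m_FO`, `r` (column names follow the default group roles).
#' @export
retention_index <- function(dmrs, mat, groups = c("LF", "HF", "FO"),
                            clip = c(-0.5, 1.5)) {
  if (length(groups) != 3L) stop("exactly three groups required")
  site_key <- paste(mat$chrom, mat$pos)
  cols <- lapply(groups, function(g) group_columns(mat, g))
  n <- nrow(dmrs)
  m <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    j <- match(paste(dmrs$chrom[i], dmrs$members[[i]]), site_key)
    if (anyNA(j)) stop("DMR member CpGs missing from the count matrix")
    for (k in 1:3) {
      tt <- sum(mat$total[j, cols[[k]], drop = FALSE])
      if (tt == 0) stop("DMR without coverage in a group")
      m[i, k] <- sum(mat$meth[j, cols[[k]], drop = FALSE]) / tt
    }
  }
  denom <- m[, 2L] - m[, 1L]
  r <- ifelse(denom == 0, NA_real_,
              pmin(clip[2L], pmax(clip[1L], (m[, 3L] - m[, 1L]) / denom)))
  out <- data.frame(
    dmr_id = if (!is.null(dmrs$dmr_id)) dmrs$dmr_id else
      paste0("dmr_", seq_len(n)),
    direction = if (!is.null(dmrs$direction)) dmrs$direction else
      NA_character_,
    m_LF = m[, 1L], m_HF = m[, 2L], m_FO = m[, 3L], r = r,
    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(r))
  out
}

#' Classify DMR persistence from the retention index
#'
#' `retained` when `r >= retained_min`, `lost` when `r <= lost_max`,
#' `intermediate` otherwise; the three classes partition all defined calls.
#'
#' @param calls output of [retention_index()].
#' @param retained_min,lost_max class thresholds (must satisfy
#'   `lost_max < retained_min`).
#' @return list with `calls` (input plus `class`) and `summary`, a
#'   direction x class count table.
#' @export
classify_persistence <- function(calls, retained_min = 0.7, lost_max = 0.3) {
  if (lost_max >= retained_min) stop("thresholds inverted")
  cls <- ifelse(is.na(calls$r), NA_character_,
                ifelse(calls$r >= retained_min, "retained",
                       ifelse(calls$r <= lost_max, "lost", "intermediate")))
  calls$class <- cls
  summary <- as.data.frame(table(direction = calls$direction,
                                 class = factor(cls, levels = c(
                                   "retained", "lost", "intermediate"))),
                           stringsAsFactors = FALSE)
  list(calls = calls, summary = summary)
}

#' Cluster DMRs by their three-group methylation profiles
#'
#' K-means (multiple restarts, seeded) on the `(m_LF, m_HF, m_FO)` triples,
#' relabelled `C1..Ck` by descending mean retention index so that `C1`
#' collects the most retained DMRs.  When fewer distinct profiles than `k`
#' exist, the effective number of clusters is reduced with a warning.
#'
#' @param calls output of [retention_index()].
#' @param k number of clusters (default 6).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return `calls` with an added `cluster` factor; attributes `"centers"`
#'   and `"cluster_mean_r"`.
#' @export
cluster_dmrs <- function(calls, k = 6, seed = 1, nstart = 25) {
  x <- as.matrix(calls[, c("m_LF", "m_HF", "m_FO")])
  if (k > nrow(x)) stop("k exceeds the number of DMRs")
  k_eff <- min(k, nrow(unique(x)))
  if (k_eff < k) {
    warning(sprintf("only %d distinct profiles; using %d cluster(s)",
                    k_eff, k_eff))
  }
  set.seed(seed)
  km <- kmeans(x, centers = k_eff, nstart = nstart)
  mean_r <- vapply(seq_len(k_eff), function(cl)
    mean(calls$r[km$cluster == cl], na.rm = TRUE), 0)
  ord <- order(-mean_r)
  relabel <- integer(k_eff)
  relabel[ord] <- seq_len(k_eff)
  labels <- paste0("C", relabel[km$cluster])
  calls$cluster <- factor(labels, levels = paste0("C", seq_len(k_eff)))
  attr(calls, "centers") <- km$centers[ord, , drop = FALSE]
  attr(calls, "cluster_mean_r") <- mean_r[ord]
  calls
}
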