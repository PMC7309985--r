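#' Sampling workspace for permutation enrichment
#'
#' The workspace is the portion of the genome within which randomized
#' segments may be placed (typically whole contigs minus assembly gaps).
#' Intervals are unioned into a sorted, disjoint set on construction.
#'
#' @param intervals interval data.frame (see [genomic_intervals()]).
#' @return a list of class `workspace` with the disjoint `intervals` and
#'   `total_nt`.
#' @export
workspace <- function(intervals) {
  u <- iv_union(intervals)
  if (nrow(u) == 0 || sum(u$end - u$start) <= 0)
    stop("workspace must have positive total length")
  w <- list(intervals = u, total_nt = sum(u$end - u$start))
  class(w) <- "workspace"
  w
}

# placement table for one segment length: which workspace intervals can
# hold it and how many valid starts each offers
placement_table <- function(ws, len) {
  n_valid <- pmax(0, (ws$intervals$end - ws$intervals$start) - len + 1)
  if (all(n_valid == 0))
    stop("segment of length ", len, " is longer than every workspace interval")
  list(cum = cumsum(n_valid), total = sum(n_valid))
}

# draw n placements of a segment of length `len`: returns start positions
# and contigs. Interval chosen with probability proportional to its number
# of valid starts; start uniform among them.
draw_placements <- function(ws, len, n) {
  pt <- placement_table(ws, len)
  u <- floor(stats::runif(n) * pt$total)       # 0 .. total-1
  u[u >= pt$total] <- pt$total - 1             # guard fp edge
  idx <- findInterval(u, pt$cum) + 1L          # workspace interval index
  prev <- c(0, pt$cum)[idx]
  offs <- u - prev
  list(contig = ws$intervals$contig[idx],
       start = ws$intervals$start[idx] + offs)
}

#' Randomly relocate segments within a workspace
#'
#' Each segment is independently relocated, preserving its length: a
#' workspace interval is chosen with probability proportional to the
#' number of valid start positions it offers, and the start is uniform
#' among those positions. Sampled segments may overlap each other.
#'
#' @param segments interval data.frame of segments to relocate.
#' @param ws a [workspace()].
#' @param seed integer seed fixing the placement (optional; when missing
#'   the current RNG stream is used).
#' @return interval data.frame of the relocated segments (same lengths,
#'   same order).
#' @export
permute_segments <- function(segments, ws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- segments$end - segments$start
  contig <- character(nrow(segments))
  start <- numeric(nrow(segments))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    pl <- draw_placements(ws, L, length(sel))
    contig[sel] <- pl$contig
    start[sel] <- pl$start
  }
  data.frame(contig = contig, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

#' Nucleotides of overlap between two interval sets
#'
#' `|union(segments) n union(annotation)|` in nucleotides.
#'
#' @param segments,annotation interval data.frames.
#' @return a single nucleotide count.
#' @export
overlap_nucleotides <- function(segments, annotation) {
  iv_total_nt(iv_intersect(segments, annotation))
}

#' Permutation test of interval overlap enrichment
#'
#' Compares the observed nucleotide overlap between `segments` and
#' `annotation` with its null distribution obtained by randomly relocating
#' the segments within the workspace `n_samples` times. Reports the null
#' mean (`expected`), fold change `observed/expected`, the empirical
#' p-value in the observed direction (with floor `1/n_samples`), and both
#' fixed-direction one-sided p-values (`p_enriched`, `p_depleted`) for
#' calibration use.
#'
#' @param segments interval data.frame (e.g. SV intervals of one class).
#' @param annotation interval data.frame (e.g. one repeat family track).
#' @param ws a [workspace()] both sets live in.
#' @param n_samples number of random placements (default 10000, giving the
#'   conventional p-value floor of 1e-04; must be at least 100).
#' @param seed integer seed for reproducible sampling.
#' @return a list of class `enrichment_result`.
#' @export
enrichment_test <- function(segments, annotation, ws, n_samples = 10000L,
                            seed = NULL) {
  if (n_samples < 100) stop("n_samples must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  observed <- overlap_nucleotides(segments, annotation)

  # null: sum over segments of overlap with the annotation union, using a
  # cumulative-coverage lookup (segments are placed independently, so the
  # null statistic is the sum of per-segment overlaps)
  covf <- coverage_prefix(annotation)
  lens <- segments$end - segments$start
  null_overlap <- numeric(n_samples)
  for (L in unique(lens)) {
    k <- sum(lens == L)
    for (rep_i in seq_len(k)) {
      pl <- draw_placements(ws, L, n_samples)
      ov <- numeric(n_samples)
      for (ctg in unique(pl$contig)) {
        sel <- pl$contig == ctg
        ov[sel] <- covf(ctg, pl$start[sel] + L) - covf(ctg, pl$start[sel])
      }
      null_overlap <- null_overlap + ov
    }
  }
  expected <- mean(null_overlap)
  n_ge <- sum(null_overlap >= observed)
  n_le <- sum(null_overlap <= observed)
  p_enr <- max(n_ge, 1L) / n_samples
  p_dep <- max(n_le, 1L) / n_samples
  if (expected == 0 && observed == 0) {
    res <- list(observed_overlap = 0, expected_overlap = 0,
                fold_change = NA_real_, p_empirical = NA_real_,
                p_enriched = NA_real_, p_depleted = NA_real_,
                direction = "none", n_samples = n_samples,
                untestable = TRUE)
    class(res) <- "enrichment_result"
    return(res)
  }
  direction <- if (observed >= expected) "enriched" else "depleted"
  fold <- if (expected == 0) Inf else observed / expected
  p <- if (expected == 0) 1 / n_samples else {
    if (direction == "enriched") p_enr else p_dep
  }
  res <- list(observed_overlap = observed, expected_overlap = expected,
              fold_change = fold, p_empirical = p,
              p_enriched = p_enr, p_depleted = p_dep,
              direction = direction, n_samples = n_samples,
              untestable = FALSE)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed %.0f nt, expected %.2f nt, fold %.3f, p = %.3g (%s, %d samples)\n",
    x$observed_overlap, x$expected_overlap, x$fold_change, x$p_empirical,
    x$direction, x$n_samples))
  invisible(x)
}
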