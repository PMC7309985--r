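#' Genomic interval tables
#'
#' Intervals throughout the package use the BED convention: 0-based,
#' half-open `[start, end)`. `end - start` is the interval length in
#' nucleotides. External formats with 1-based inclusive coordinates (VCF,
#' Breakdancer output, RepeatMasker `.out`) are converted on read.
#'
#' @param contig character vector of contig names (non-empty).
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, exclusive end.
#' @return A data.frame with columns `contig`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(contig, start, end) {
  iv <- data.frame(contig = as.character(contig),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, allow_empty_span = FALSE) {
  stopifnot(is.data.frame(iv), all(c("contig", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(is.na(iv$contig)) || any(!nzchar(iv$contig)))
    stop("interval contig must be non-empty")
  if (any(is.na(iv$start)) || any(is.na(iv$end)))
    stop("interval coordinates must not be NA")
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  bad <- if (allow_empty_span) iv$end < iv$start else iv$end <= iv$start
  if (any(bad)) stop("interval end must exceed start")
  invisible(iv)
}

iv_width <- function(iv) iv$end - iv$start

iv_sort <- function(iv) {
  iv[order(iv$contig, iv$start, iv$end), , drop = FALSE]
}

#' Union (merge) of an interval set
#'
#' Collapses overlapping or book-ended intervals per contig into a sorted,
#' disjoint set.
#'
#' @param iv interval data.frame (see [genomic_intervals()]).
#' @return sorted, disjoint interval data.frame.
#' @export
iv_union <- function(iv) {
  if (nrow(iv) == 0) return(iv[, c("contig", "start", "end")])
  iv <- iv_sort(iv[, c("contig", "start", "end")])
  out <- vector("list", length(unique(iv$contig)))
  k <- 0L
  for (ctg in unique(iv$contig)) {
    x <- iv[iv$contig == ctg, , drop = FALSE]
    # running maximum of ends; a new run starts where start > max(end) so far
    cummax_end <- cummax(x$end)
    new_run <- c(TRUE, x$start[-1] > cummax_end[-nrow(x)])
    run <- cumsum(new_run)
    k <- k + 1L
    out[[k]] <- data.frame(
      contig = ctg,
      start = tapply(x$start, run, min),
      end = tapply(x$end, run, max),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Intersection of two interval sets
#'
#' @param a,b interval data.frames; each is unioned internally first.
#' @return sorted, disjoint interval data.frame covering `union(a)` \eqn{\cap}
#'   `union(b)`.
#' @export
iv_intersect <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  empty <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  pieces <- list(empty)
  for (ctg in intersect(unique(a$contig), unique(b$contig))) {
    x <- a[a$contig == ctg, ]; y <- b[b$contig == ctg, ]
    # two-pointer sweep over sorted disjoint sets
    i <- 1L; j <- 1L; s <- numeric(0); e <- numeric(0)
    while (i <= nrow(x) && j <= nrow(y)) {
      lo <- max(x$start[i], y$start[j])
      hi <- min(x$end[i], y$end[j])
      if (hi > lo) { s <- c(s, lo); e <- c(e, hi) }
      if (x$end[i] < y$end[j]) i <- i + 1L else j <- j + 1L
    }
    if (length(s))
      pieces[[length(pieces) + 1L]] <- data.frame(contig = ctg, start = s,
                                                  end = e, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Complement of an interval set within a genome space
#'
#' @param iv interval data.frame.
#' @param genome interval data.frame of the full space (e.g. whole contigs).
#' @return intervals covering `union(genome)` minus `union(iv)`.
#' @export
iv_complement <- function(iv, genome) {
  genome <- iv_union(genome)
  iv <- iv_intersect(iv, genome)
  if (nrow(iv) == 0) return(genome)
  pieces <- list()
  for (ctg in unique(genome$contig)) {
    g <- genome[genome$contig == ctg, ]
    x <- iv[iv$contig == ctg, ]
    for (r in seq_len(nrow(g))) {
      xs <- x[x$end > g$start[r] & x$start < g$end[r], ]
      bounds <- c(g$start[r], rbind(xs$start, xs$end), g$end[r])
      s <- bounds[seq(1, length(bounds) - 1, by = 2)]
      e <- bounds[seq(2, length(bounds), by = 2)]
      keep <- e > s
      if (any(keep))
        pieces[[length(pieces) + 1L]] <- data.frame(contig = ctg, start = s[keep],
                                                    end = e[keep],
                                                    stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces))
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  res <- iv_sort(do.call(rbind, pieces))
  rownames(res) <- NULL
  res
}

iv_total_nt <- function(iv) {
  u <- iv_union(iv)
  if (nrow(u) == 0) 0 else sum(u$end - u$start)
}

# vectorized reciprocal overlap on parallel coordinate vectors (same contig
# assumed); returns 0 where intervals are disjoint
ro_vec <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(inter / (e1 - s1), inter / (e2 - s2))
}

#' Reciprocal overlap fraction of two intervals
#'
#' The fraction `min(|a n b| / |a|, |a n b| / |b|)` used by the consensus
#' merging steps; "at least 90% reciprocal" means this value is >= 0.9.
#' Returns 0 when the intervals lie on different contigs.
#'
#' @param a,b single intervals: 1-row data.frames or lists with `contig`,
#'   `start`, `end`.
#' @return a fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' reciprocal_overlap(genomic_intervals("c", 100, 200),
#'                    genomic_intervals("c", 150, 250))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (a$end - a$start <= 0 || b$end - b$start <= 0)
    stop("reciprocal overlap is undefined for zero-length intervals")
  if (a$contig != b$contig) return(0)
  ro_vec(a$start, a$end, b$start, b$end)
}

# cumulative-coverage lookup for fast overlap-with-union queries.
# Returns a function F(contig, pos) = nucleotides of the union in [0, pos).
coverage_prefix <- function(iv) {
  u <- iv_union(iv)
  tabs <- lapply(split(u, u$contig), function(x) {
    list(starts = x$start, ends = x$end, cumw = c(0, cumsum(x$end - x$start)))
  })
  function(contig, pos) {
    t <- tabs[[contig]]
    if (is.null(t)) return(numeric(length(pos)) * 0)
    # index of last interval whose start <= pos
    idx <- findInterval(pos, t$starts)
    covered <- t$cumw[idx + 1L]
    # subtract the part of interval idx beyond pos
    has <- idx > 0L
    if (any(has)) {
      over <- pmax(0, t$ends[idx[has]] - pos[has])
      within <- pmin(over, t$ends[idx[has]] - t$starts[idx[has]])
      covered[has] <- covered[has] - within
    }
    covered
  }
}
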