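REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "RC", "Simple_repeat",
                    "Low_complexity", "Satellite", "Unknown", "Other")

#' Parse a RepeatMasker `.out` annotation file
#'
#' Standard layout: 3 header lines followed by whitespace-separated rows
#' with the Smith-Waterman score, percent divergence from the consensus,
#' deletion/insertion percentages, query sequence and 1-based inclusive
#' coordinates, strand, repeat name and class/family. The repeat class is
#' the part of the class/family column before `/`; unrecognised classes
#' map to `Other`. Malformed rows are skipped with a warning.
#'
#' @param path `.out` file path.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `repeat_class`, `family`, `divergence`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(contig = character(), start = numeric(),
                      end = numeric(), repeat_class = character(),
                      family = character(), divergence = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  ok <- lengths(fields) >= 11
  div <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, "")))
  beg <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 6) f[6] else NA_character_, "")))
  end <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 7) f[7] else NA_character_, "")))
  ok <- ok & !is.na(div) & !is.na(beg) & !is.na(end) & div >= 0 & div <= 100
  if (any(!ok))
    warning(sum(!ok), " malformed RepeatMasker row(s) skipped")
  if (!any(ok)) return(empty)
  fields <- fields[ok]
  classfam <- vapply(fields, `[[`, "", 11L)
  cls <- sub("/.*$", "", classfam)
  cls[!cls %in% REPEAT_CLASSES] <- "Other"
  out <- data.frame(
    contig = vapply(fields, `[[`, "", 5L),
    start = beg[ok] - 1, end = end[ok],
    repeat_class = cls,
    family = classfam,
    divergence = div[ok],
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write repeat elements in RepeatMasker `.out` layout
#'
#' Inverse of [parse_repeatmasker_out()]; used by the synthetic-data
#' generator.
#'
#' @param repeats data.frame as returned by [parse_repeatmasker_out()].
#' @param path output file path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query                 position in query     matching  repeat                position in repeat",
    "score   div. del. ins.  sequence              begin    end   (left) repeat    class/family        begin   end  (left)  ID",
    "")
  if (nrow(repeats) == 0) { writeLines(hdr, path); return(invisible(path)) }
  repeats <- repeats[order(repeats$contig, repeats$start, repeats$end), ]
  lines <- sprintf(
    "  %3d  %5.1f  0.0  0.0  %s  %d  %d  (0) + %s  %s  1  %d  (0)  %d",
    250L, repeats$divergence, repeats$contig, repeats$start + 1, repeats$end,
    sub("/.*$", "", repeats$family), repeats$family,
    repeats$end - repeats$start, seq_len(nrow(repeats)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Repeat divergence landscape inside and outside SV space
#'
#' For each region (`inside` the union of the SV intervals, `outside` =
#' its complement within the genome workspace), each repeat class and each
#' divergence bin, reports the proportion of the region's nucleotides
#' covered by repeats of that class and bin. Only repeats fully contained
#' in the region are counted, so elements straddling an SV boundary
#' contribute to neither region and totals need not sum to the genome-wide
#' repeat content. Divergence bins are `[0, bin_width)`,
#' `[bin_width, 2 bin_width)`, ... up to 100%.
#'
#' @param sv_space interval data.frame of SV intervals (within `genome`).
#' @param repeats data.frame from [parse_repeatmasker_out()].
#' @param genome a [workspace()] describing the genomic space considered.
#' @param bin_width divergence bin width in percent (default 5).
#' @return data.frame with columns `region`, `bin_low`, `bin_high`,
#'   `repeat_class`, `nt`, `proportion`.
#' @export
repeat_landscape <- function(sv_space, repeats, genome, bin_width = 5) {
  if (100 %% bin_width != 0)
    warning("bin_width does not divide 100; the last bin is truncated")
  inside <- iv_intersect(sv_space, genome$intervals)
  outside <- iv_complement(sv_space, genome$intervals)
  breaks <- unique(c(seq(0, 100, by = bin_width), 100))
  bin_of <- function(d) pmin(findInterval(d, breaks,
                                          rightmost.closed = TRUE),
                             length(breaks) - 1)
  region_rows <- function(region_iv, label) {
    total <- iv_total_nt(region_iv)
    contained <- rep(FALSE, nrow(repeats))
    if (nrow(region_iv) && nrow(repeats)) {
      for (ctg in unique(region_iv$contig)) {
        u <- region_iv[region_iv$contig == ctg, ]
        sel <- which(repeats$contig == ctg)
        if (!length(sel)) next
        idx <- findInterval(repeats$start[sel], u$start)
        inside_one <- idx > 0 & repeats$end[sel] <= u$end[pmax(idx, 1)]
        contained[sel] <- inside_one
      }
    }
    grid <- expand.grid(bin = seq_len(length(breaks) - 1),
                        repeat_class = REPEAT_CLASSES,
                        stringsAsFactors = FALSE)
    nt <- numeric(nrow(grid))
    if (any(contained)) {
      rr <- repeats[contained, ]
      key <- paste(bin_of(rr$divergence), rr$repeat_class)
      agg <- tapply(rr$end - rr$start, key, sum)
      gkey <- paste(grid$bin, grid$repeat_class)
      nt[match(names(agg), gkey)] <- agg
    }
    data.frame(region = label,
               bin_low = breaks[grid$bin], bin_high = breaks[grid$bin + 1],
               repeat_class = grid$repeat_class, nt = nt,
               proportion = if (total > 0) nt / total else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(region_rows(inside, "inside"), region_rows(outside, "outside"))
  rownames(out) <- NULL
  out
}

#' Read whole-genome alignment blocks from a 6-column BED-like file
#'
#' Columns: reference contig, reference start, reference end (0-based
#' half-open), `query_contig:query_start-query_end`, chain id, strand.
#'
#' @param path file path.
#' @return alignment block data.frame (see [alignment_blocks()]).
#' @export
read_alignment_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(alignment_blocks(character(), numeric(), numeric(), character(),
                            numeric(), numeric(), character(), character()))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character", "character"),
                          stringsAsFactors = FALSE)
  q <- regmatches(df$V4, regexec("^(.+):([0-9]+)-([0-9]+)$", df$V4))
  if (any(lengths(q) != 4)) stop("malformed query locus in ", path)
  alignment_blocks(df$V1, df$V2, df$V3,
                   vapply(q, `[[`, "", 2), as.numeric(vapply(q, `[[`, "", 3)),
                   as.numeric(vapply(q, `[[`, "", 4)), df$V6, df$V5)
}

#' Write alignment blocks in the 6-column BED-like layout
#'
#' @param blocks alignment block data.frame.
#' @param path output file path.
#' @export
write_alignment_bed <- function(blocks, path) {
  if (nrow(blocks) == 0) { writeLines(character(0), path); return(invisible(path)) }
  lines <- paste(blocks$ref_contig,
                 format(blocks$ref_start, scientific = FALSE, trim = TRUE),
                 format(blocks$ref_end, scientific = FALSE, trim = TRUE),
                 sprintf("%s:%s-%s", blocks$q_contig,
                         format(blocks$q_start, scientific = FALSE, trim = TRUE),
                         format(blocks$q_end, scientific = FALSE, trim = TRUE)),
                 blocks$chain_id, blocks$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Build a table of colinear whole-genome alignment blocks
#'
#' Each block maps a reference interval to an equal-length query interval
#' on a strand; blocks sharing a `chain_id` must be colinear (sorted,
#' non-overlapping in the reference, and consistently ordered in the
#' query: same order on `+`, reversed on `-`).
#'
#' @param ref_contig,ref_start,ref_end reference interval (0-based
#'   half-open).
#' @param q_contig,q_start,q_end query interval.
#' @param strand `"+"` or `"-"`.
#' @param chain_id chain identifier grouping colinear blocks.
#' @return a data.frame of class `alignment_blocks`.
#' @export
alignment_blocks <- function(ref_contig, ref_start, ref_end, q_contig,
                             q_start, q_end, strand, chain_id) {
  df <- data.frame(ref_contig = as.character(ref_contig),
                   ref_start = as.numeric(ref_start),
                   ref_end = as.numeric(ref_end),
                   q_contig = as.character(q_contig),
                   q_start = as.numeric(q_start),
                   q_end = as.numeric(q_end),
                   strand = as.character(strand),
                   chain_id = as.character(chain_id),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any((df$ref_end - df$ref_start) != (df$q_end - df$q_start)))
      stop("alignment blocks must have equal reference and query lengths")
    if (any(!df$strand %in% c("+", "-"))) stop("strand must be + or -")
    validate_chains(df)
  }
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

validate_chains <- function(df) {
  for (cid in unique(df$chain_id)) {
    b <- df[df$chain_id == cid, ]
    b <- b[order(b$ref_start), ]
    if (length(unique(b$ref_contig)) > 1 || length(unique(b$q_contig)) > 1 ||
        length(unique(b$strand)) > 1)
      stop("inconsistent chain ", cid, ": mixed contigs or strands")
    if (nrow(b) > 1) {
      if (any(b$ref_start[-1] < b$ref_end[-nrow(b)]))
        stop("inconsistent chain ", cid, ": overlapping reference blocks")
      qo <- if (b$strand[1] == "+") b$q_start else rev(b$q_start)
      if (is.unsorted(qo, strictly = TRUE))
        stop("inconsistent chain ", cid, ": non-colinear query blocks")
    }
  }
  invisible(df)
}

#' Deletion concordance with whole-genome alignments
#'
#' A predicted deletion is discordant with the alignments when at least
#' one alignment block spans 50% or more of the predicted deleted region
#' (sequence predicted absent in the query should not align across the
#' region). Reports a per-deletion verdict and the overall discordant
#' fraction.
#'
#' @param deletions [consensus_svs()] (or any interval table with a
#'   `consensus_id` column) of DEL events in reference coordinates.
#' @param blocks [alignment_blocks()] in the same reference coordinates.
#' @param min_span_fraction block span triggering discordance
#'   (default 0.5).
#' @return list with `verdicts` (data.frame: consensus_id, max_span_fraction,
#'   discordant), `discordant_count` and `discordant_fraction`.
#' @export
deletion_concordance <- function(deletions, blocks, min_span_fraction = 0.5) {
  if (nrow(deletions) && any(deletions$end <= deletions$start))
    stop("zero-length deletion interval")
  frac <- numeric(nrow(deletions))
  for (i in seq_len(nrow(deletions))) {
    b <- blocks[blocks$ref_contig == deletions$contig[i], , drop = FALSE]
    if (!nrow(b)) next
    ov <- pmax(0, pmin(b$ref_end, deletions$end[i]) -
                 pmax(b$ref_start, deletions$start[i]))
    frac[i] <- max(ov) / (deletions$end[i] - deletions$start[i])
  }
  discordant <- frac >= min_span_fraction
  list(verdicts = data.frame(consensus_id = deletions$consensus_id,
                             max_span_fraction = frac,
                             discordant = discordant,
                             stringsAsFactors = FALSE),
       discordant_count = sum(discordant),
       discordant_fraction = if (nrow(deletions)) mean(discordant) else NA_real_)
}

#' Lift a reference interval to query coordinates through alignment chains
#'
#' An interval maps iff its first and last base both fall inside blocks of
#' the same chain; per-block offsets are applied, and on `-` strand the
#' output interval is mirrored in query coordinates. Intervals whose
#' endpoints are unaligned (or that span two chains) are unmapped.
#'
#' @param iv single interval (1-row data.frame or list with `contig`,
#'   `start`, `end`).
#' @param blocks [alignment_blocks()].
#' @return interval data.frame in query coordinates, or `NULL` when
#'   unmapped.
#' @export
liftover_interval <- function(iv, blocks) {
  iv <- as.list(iv)
  s <- iv$start; last <- iv$end - 1
  for (cid in unique(blocks$chain_id[blocks$ref_contig == iv$contig])) {
    b <- blocks[blocks$chain_id == cid & blocks$ref_contig == iv$contig, ,
                drop = FALSE]
    bs <- b[b$ref_start <= s & s < b$ref_end, , drop = FALSE]
    be <- b[b$ref_start <= last & last < b$ref_end, , drop = FALSE]
    if (nrow(bs) != 1 || nrow(be) != 1) next
    if (bs$strand == "+") {
      qs <- bs$q_start + (s - bs$ref_start)
      qe <- be$q_start + (last - be$ref_start) + 1
    } else {
      qs <- be$q_end - 1 - (last - be$ref_start)
      qe <- bs$q_end - (s - bs$ref_start)
    }
    if (qe <= qs) next  # degenerate ordering across blocks
    return(data.frame(contig = bs$q_contig, start = qs, end = qe,
                      strand = bs$strand, chain_id = cid,
                      stringsAsFactors = FALSE))
  }
  NULL
}

#' Invert alignment chains (swap reference and query)
#'
#' Lifting an interval through a chain and back through the inverted
#' chain is the identity for mapped intervals.
#'
#' @param blocks [alignment_blocks()].
#' @return [alignment_blocks()] with reference and query swapped (strand
#'   preserved).
#' @export
invert_chain <- function(blocks) {
  alignment_blocks(blocks$q_contig, blocks$q_start, blocks$q_end,
                   blocks$ref_contig, blocks$ref_start, blocks$ref_end,
                   blocks$strand, blocks$chain_id)
}
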