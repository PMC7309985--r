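#' Per-caller quality filter thresholds
#'
#' Defaults follow the standard multi-caller filtering recipe: calls must
#' be supported by at least 2 libraries and 5 discordantly mapping read
#' pairs (Breakdancer and Pindel), carry the maximum Breakdancer confidence
#' score of 99, and for Delly both a PASS filter and a PRECISE breakpoint
#' flag. Deletions are additionally subject to a 1 kb minimum size floor,
#' which counters the small-deletion excess typical of read-pair callers.
#'
#' @param min_libraries minimum distinct supporting libraries (default 2).
#' @param min_read_pairs minimum discordant read pairs (default 5).
#' @param breakdancer_min_score minimum Breakdancer score (default 99,
#'   Breakdancer's maximum, so effectively an equality).
#' @param require_delly_pass require FILTER == PASS for Delly (default TRUE).
#' @param require_delly_precise require the PRECISE flag for Delly
#'   (default TRUE).
#' @param min_deletion_size minimum deletion length in nt (default 1000,
#'   boundary inclusive: a 1000 nt deletion is kept).
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_libraries = 2L, min_read_pairs = 5L,
                              breakdancer_min_score = 99,
                              require_delly_pass = TRUE,
                              require_delly_precise = TRUE,
                              min_deletion_size = 1000L) {
  t <- list(min_libraries = as.integer(min_libraries),
            min_read_pairs = as.integer(min_read_pairs),
            breakdancer_min_score = as.numeric(breakdancer_min_score),
            require_delly_pass = isTRUE(require_delly_pass),
            require_delly_precise = isTRUE(require_delly_precise),
            min_deletion_size = as.integer(min_deletion_size))
  if (any(unlist(t[c(1, 2, 3, 6)]) < 0)) stop("thresholds must be >= 0")
  class(t) <- "filter_thresholds"
  t
}

filter_keep <- function(records, keep, label) {
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(filter = label,
                                      n_in = nrow(records),
                                      n_kept = sum(keep),
                                      n_rejected = sum(!keep),
                                      stringsAsFactors = FALSE)
  out
}

#' Filter Breakdancer calls on library, read-pair and score support
#'
#' Keeps records with `n_libraries >= min_libraries`, `n_read_pairs >=
#' min_read_pairs` and `score >= breakdancer_min_score`. Records with a
#' missing score are rejected and counted in the rejection summary
#' (attribute `"rejected"`).
#'
#' @param records [sv_records()] with caller `breakdancer`.
#' @param t a [filter_thresholds()] object.
#' @return the kept subset, with a `"rejected"` summary attribute.
#' @export
filter_breakdancer <- function(records, t = filter_thresholds()) {
  stopifnot(all(records$caller == "breakdancer"))
  keep <- records$n_libraries >= t$min_libraries &
    records$n_read_pairs >= t$min_read_pairs &
    !is.na(records$score) & records$score >= t$breakdancer_min_score
  filter_keep(records, keep, "breakdancer")
}

#' Filter Pindel calls on library and read-pair support
#'
#' Keeps records with `n_libraries >= min_libraries` and `n_read_pairs >=
#' min_read_pairs`; Pindel's confidence fields have no normalized score, so
#' no score criterion is applied.
#'
#' @inheritParams filter_breakdancer
#' @param records [sv_records()] with caller `pindel`.
#' @export
filter_pindel <- function(records, t = filter_thresholds()) {
  stopifnot(all(records$caller == "pindel"))
  keep <- records$n_libraries >= t$min_libraries &
    records$n_read_pairs >= t$min_read_pairs
  filter_keep(records, keep, "pindel")
}

#' Filter Delly calls on the PASS and PRECISE flags
#'
#' Keeps records with `filter_pass` and `precise` both TRUE (when the
#' corresponding requirement is enabled). Library/read-pair thresholds are
#' not applied to Delly.
#'
#' @inheritParams filter_breakdancer
#' @param records [sv_records()] with caller `delly`.
#' @export
filter_delly <- function(records, t = filter_thresholds()) {
  stopifnot(all(records$caller == "delly"))
  keep <- (!t$require_delly_pass | records$filter_pass) &
    (!t$require_delly_precise | records$precise)
  filter_keep(records, keep, "delly")
}

#' Apply the per-caller filter appropriate for each record's caller
#'
#' @inheritParams filter_breakdancer
#' @param records [sv_records()] from a single caller.
#' @export
filter_caller <- function(records, t = filter_thresholds()) {
  caller <- unique(records$caller)
  if (length(caller) > 1) stop("records must come from a single caller")
  if (!length(caller)) return(records)
  switch(caller,
         breakdancer = filter_breakdancer(records, t),
         pindel = filter_pindel(records, t),
         delly = filter_delly(records, t),
         filter_keep(records, rep(TRUE, nrow(records)), caller))
}

#' Remove deletions below the minimum size floor
#'
#' DEL events shorter than `min_deletion_size` are removed; all other SV
#' classes pass through untouched. The floor is boundary inclusive: a
#' deletion of exactly the minimum size is kept.
#'
#' @param svs [sv_records()] or [consensus_svs()] table.
#' @param t a [filter_thresholds()] object.
#' @return the same type of table, filtered.
#' @export
filter_deletion_size <- function(svs, t = filter_thresholds()) {
  keep <- svs$sv_class != "DEL" | (svs$end - svs$start) >= t$min_deletion_size
  filter_keep(svs, keep, "deletion_size")
}
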