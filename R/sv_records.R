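#' Supported structural-variant classes
#'
#' Deletions (DEL), duplications (DUP), inversions (INV), insertions (INS)
#' and translocations (TRA), called relative to a common reference genome.
#'
#' @export
SV_CLASSES <- c("DEL", "DUP", "INV", "INS", "TRA")

#' Recognised SV caller identifiers
#' @export
SV_CALLERS <- c("breakdancer", "delly", "pindel", "other")

#' Build a table of per-caller SV records
#'
#' One row per raw call from one caller in one species. Coordinates are
#' 0-based half-open. Insertions are represented as 1-nt breakpoint
#' intervals with the inserted size in `insertion_length`; translocations
#' carry a mate breakpoint in `mate_contig`/`mate_start`/`mate_end`.
#'
#' @param contig,start,end interval of the event (see [genomic_intervals()]).
#' @param sv_class one of [SV_CLASSES].
#' @param species species identifier.
#' @param caller caller identifier (one of [SV_CALLERS]).
#' @param n_libraries number of distinct sequencing libraries supporting the
#'   call (default 0).
#' @param n_read_pairs number of discordantly mapping read pairs supporting
#'   the call (default 0).
#' @param score caller confidence score, `NA` where the caller provides none.
#' @param filter_pass logical, `TRUE` for a PASS FILTER field.
#' @param precise logical, `TRUE` for a PRECISE breakpoint flag.
#' @param insertion_length inserted size in nt (INS only, else 0).
#' @param mate_contig,mate_start,mate_end mate breakpoint (TRA only).
#' @param record_id unique record identifier; autogenerated when missing.
#' @return a data.frame of class `sv_records`.
#' @export
sv_records <- function(contig, start, end, sv_class, species, caller,
                       n_libraries = 0L, n_read_pairs = 0L, score = NA_real_,
                       filter_pass = TRUE, precise = TRUE,
                       insertion_length = 0L,
                       mate_contig = NA_character_, mate_start = NA_real_,
                       mate_end = NA_real_, record_id = NULL) {
  n <- length(start)
  df <- data.frame(
    contig = rep_len(as.character(contig), n),
    start = as.numeric(start),
    end = as.numeric(end),
    sv_class = rep_len(as.character(sv_class), n),
    species = rep_len(as.character(species), n),
    caller = rep_len(as.character(caller), n),
    n_libraries = rep_len(as.integer(n_libraries), n),
    n_read_pairs = rep_len(as.integer(n_read_pairs), n),
    score = rep_len(as.numeric(score), n),
    filter_pass = rep_len(as.logical(filter_pass), n),
    precise = rep_len(as.logical(precise), n),
    insertion_length = rep_len(as.integer(insertion_length), n),
    mate_contig = rep_len(as.character(mate_contig), n),
    mate_start = rep_len(as.numeric(mate_start), n),
    mate_end = rep_len(as.numeric(mate_end), n),
    stringsAsFactors = FALSE)
  df$record_id <- if (is.null(record_id)) {
    sprintf("%s_%s_%06d", df$species, df$caller, seq_len(n))
  } else rep_len(as.character(record_id), n)
  validate_sv_records(df)
  class(df) <- c("sv_records", "data.frame")
  df
}

validate_sv_records <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad_class <- setdiff(unique(df$sv_class), SV_CLASSES)
  if (length(bad_class))
    stop("unknown SV class: ", paste(bad_class, collapse = ", "))
  validate_intervals(df)
  span <- !df$sv_class %in% c("INS", "TRA")
  if (any(span & (df$end - df$start) < 1))
    stop("span events (DEL/DUP/INV) must have length >= 1")
  if (any(df$sv_class == "TRA" & is.na(df$mate_contig)))
    stop("TRA records must carry a mate breakpoint")
  if (anyDuplicated(df$record_id))
    stop("record_id values must be unique")
  invisible(df)
}

empty_sv_records <- function() {
  sv_records(character(), numeric(), numeric(), character(), character(),
             character())
}

#' Sort SV records by (contig, start, end, record_id)
#'
#' The canonical record order used by all readers and merge operations.
#'
#' @param df [sv_records()] table.
#' @return the sorted table with reset row names.
#' @export
sort_sv_records <- function(df) {
  df <- df[order(df$contig, df$start, df$end, df$record_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a table of multi-caller / multi-species consensus SVs
#'
#' @param contig,start,end representative interval of the merged event.
#' @param sv_class one of [SV_CLASSES].
#' @param species_present `;`-joined sorted species identifiers.
#' @param callers_by_species per-species caller provenance, formatted
#'   `species=caller1|caller2;species2=...`.
#' @param source_records `;`-joined contributing record ids.
#' @param consensus_id unique identifier.
#' @param support total supporting read pairs over source records.
#' @return a data.frame of class `consensus_svs`.
#' @export
consensus_svs <- function(contig, start, end, sv_class, species_present,
                          callers_by_species, source_records, consensus_id,
                          support = 0L) {
  n <- length(start)
  df <- data.frame(
    contig = as.character(contig), start = as.numeric(start),
    end = as.numeric(end), sv_class = rep_len(as.character(sv_class), n),
    species_present = as.character(species_present),
    callers_by_species = as.character(callers_by_species),
    source_records = as.character(source_records),
    consensus_id = as.character(consensus_id),
    support = rep_len(as.numeric(support), n),
    stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(!nzchar(df$species_present)))
      stop("species_present must be non-empty")
    sp <- strsplit(df$species_present, ";", fixed = TRUE)
    keys <- lapply(strsplit(df$callers_by_species, ";", fixed = TRUE),
                   function(x) sort(sub("=.*", "", x)))
    if (!all(mapply(identical, lapply(sp, sort), keys)))
      stop("species_present must equal the keys of callers_by_species")
  }
  class(df) <- c("consensus_svs", "data.frame")
  df
}

n_species_of <- function(cons) {
  lengths(strsplit(cons$species_present, ";", fixed = TRUE))
}
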