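#' Convert between external 1-based inclusive and internal 0-based half-open
#' coordinates
#'
#' @param start1,end1 1-based inclusive coordinates.
#' @return data.frame with internal `start`, `end`.
#' @keywords internal
from_1based <- function(start1, end1) {
  data.frame(start = start1 - 1, end = end1)
}

to_1based <- function(start, end) {
  data.frame(start1 = start + 1, end1 = end)
}

vcf_info_get <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

vcf_info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "($|;)"), info)
}

#' Read structural-variant calls from a VCF 4.x file
#'
#' Normalizes Delly/Pindel-style SV output into the package's record table.
#' SV records must carry `SVTYPE` and `END` (or `SVLEN` for insertions) in
#' INFO. Positions are converted from 1-based to the internal 0-based
#' half-open convention; `FILTER == "PASS"` maps to `filter_pass` and the
#' `PRECISE` INFO flag to `precise`. Support metadata is read from the
#' `LIBS` (libraries) and `PE` (discordant read pairs) INFO keys when
#' present, and the confidence score from QUAL. Records with an `SVTYPE`
#' outside the supported classes are skipped with a warning.
#'
#' @param path VCF file path.
#' @param species,caller identifiers attached to every record.
#' @return [sv_records()] table sorted by (contig, start, end).
#' @export
read_sv_vcf <- function(path, species, caller) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (!length(body_idx)) return(empty_sv_records())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8))
    stop("malformed VCF line ", body_idx[which(nf < 8)[1]], " in ", path,
         ": expected at least 8 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos))
    stop("malformed VCF line ", body_idx[which(is.na(pos))[1]], " in ", path,
         ": non-numeric POS")
  id <- vapply(fields, `[[`, "", 3L)
  qual <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  filter <- vapply(fields, `[[`, "", 7L)
  info <- vapply(fields, `[[`, "", 8L)

  svtype <- vcf_info_get(info, "SVTYPE")
  known <- !is.na(svtype) & svtype %in% SV_CLASSES
  if (any(!known))
    warning(sum(!known), " VCF record(s) with unsupported SVTYPE skipped (",
            paste(unique(svtype[!known]), collapse = ","), ")")
  if (!any(known)) return(empty_sv_records())

  chrom <- chrom[known]; pos <- pos[known]; id <- id[known]
  qual <- qual[known]; filter <- filter[known]; info <- info[known]
  svtype <- svtype[known]

  end <- suppressWarnings(as.numeric(vcf_info_get(info, "END")))
  svlen <- suppressWarnings(as.numeric(vcf_info_get(info, "SVLEN")))
  libs <- suppressWarnings(as.integer(vcf_info_get(info, "LIBS")))
  pe <- suppressWarnings(as.integer(vcf_info_get(info, "PE")))
  chr2 <- vcf_info_get(info, "CHR2")

  is_ins <- svtype == "INS"
  is_tra <- svtype == "TRA"
  start0 <- pos - 1
  end0 <- ifelse(is_ins | is_tra, pos, end)
  if (any(is.na(end0)))
    stop("SV record without END in ", path, " (id ",
         id[which(is.na(end0))[1]], ")")
  ids <- ifelse(id == "." | !nzchar(id),
                sprintf("%s_%s_%06d", species, caller, seq_along(id)), id)
  rec <- sv_records(
    contig = chrom, start = start0, end = end0, sv_class = svtype,
    species = species, caller = caller,
    n_libraries = ifelse(is.na(libs), 0L, libs),
    n_read_pairs = ifelse(is.na(pe), 0L, pe),
    score = qual,
    filter_pass = filter == "PASS",
    precise = vcf_info_flag(info, "PRECISE") & !vcf_info_flag(info, "IMPRECISE"),
    insertion_length = ifelse(is_ins & !is.na(svlen), abs(svlen), 0L),
    mate_contig = ifelse(is_tra, chr2, NA_character_),
    mate_start = ifelse(is_tra, end - 1, NA_real_),
    mate_end = ifelse(is_tra, end, NA_real_),
    record_id = ids)
  sort_sv_records(rec)
}

#' Write SV records as a VCF 4.2 file
#'
#' Inverse of [read_sv_vcf()]: support metadata goes to the `LIBS`/`PE`
#' INFO keys, the score to QUAL, `filter_pass` to the FILTER column and
#' `precise` to the `PRECISE`/`IMPRECISE` flags.
#'
#' @param records [sv_records()] table.
#' @param path output file path.
#' @export
write_sv_vcf <- function(records, path) {
  records <- sort_sv_records(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Inserted length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate contig\">",
    "##INFO=<ID=LIBS,Number=1,Type=Integer,Description=\"Supporting libraries\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Supporting discordant read pairs\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(records) == 0) { writeLines(hdr, path); return(invisible(path)) }
  is_ins <- records$sv_class == "INS"
  is_tra <- records$sv_class == "TRA"
  end1 <- ifelse(is_tra, records$mate_end, records$end)
  info <- paste0(
    "SVTYPE=", records$sv_class,
    ";END=", format(end1, scientific = FALSE, trim = TRUE),
    ifelse(is_ins, paste0(";SVLEN=", records$insertion_length), ""),
    ifelse(is_tra, paste0(";CHR2=", records$mate_contig), ""),
    ";LIBS=", records$n_libraries,
    ";PE=", records$n_read_pairs,
    ifelse(records$precise, ";PRECISE", ";IMPRECISE"))
  lines <- paste(
    records$contig,
    format(records$start + 1, scientific = FALSE, trim = TRUE),
    records$record_id, "N", paste0("<", records$sv_class, ">"),
    ifelse(is.na(records$score), ".",
           format(records$score, scientific = FALSE, trim = TRUE)),
    ifelse(records$filter_pass, "PASS", "LowQual"),
    info, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read Breakdancer-style tab-separated SV output
#'
#' Expected columns: chrom, pos1, chrom2, pos2, type, size, score,
#' num_reads, libraries (formatted `libA:4|libB:3`). Positions are 1-based
#' and converted on read; `n_libraries` is the number of distinct libraries
#' listed. Types `CTX`/`ITX` map to TRA with the mate breakpoint taken from
#' (chrom2, pos2). Unknown types are skipped with a warning.
#'
#' @param path file path; lines starting with `#` are ignored.
#' @param species species identifier attached to every record.
#' @return [sv_records()] table sorted by (contig, start, end).
#' @export
read_breakdancer_tsv <- function(path, species) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_sv_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9))
    stop("malformed Breakdancer row in ", path, ": expected 9 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  chrom2 <- vapply(fields, `[[`, "", 3L)
  pos2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  type <- vapply(fields, `[[`, "", 5L)
  size <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  nreads <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 8L)))
  libs <- vapply(fields, `[[`, "", 9L)
  if (anyNA(score) || anyNA(size))
    stop("non-numeric score or size in Breakdancer input ", path)
  map <- c(DEL = "DEL", DUP = "DUP", INV = "INV", INS = "INS",
           CTX = "TRA", ITX = "TRA", TRA = "TRA")
  cls <- unname(map[type])
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " Breakdancer row(s) with unsupported type skipped (",
            paste(unique(type[is.na(cls)]), collapse = ","), ")")
    keep <- !is.na(cls)
    chrom <- chrom[keep]; pos1 <- pos1[keep]; chrom2 <- chrom2[keep]
    pos2 <- pos2[keep]; cls <- cls[keep]; size <- size[keep]
    score <- score[keep]; nreads <- nreads[keep]; libs <- libs[keep]
  }
  if (!length(cls)) return(empty_sv_records())
  n_lib <- lengths(strsplit(libs, "|", fixed = TRUE))
  is_ins <- cls == "INS"
  is_tra <- cls == "TRA"
  rec <- sv_records(
    contig = chrom, start = pos1 - 1,
    end = ifelse(is_ins | is_tra, pos1, pos2),
    sv_class = cls, species = species, caller = "breakdancer",
    n_libraries = n_lib, n_read_pairs = nreads, score = score,
    filter_pass = TRUE, precise = FALSE,
    insertion_length = ifelse(is_ins, size, 0L),
    mate_contig = ifelse(is_tra, chrom2, NA_character_),
    mate_start = ifelse(is_tra, pos2 - 1, NA_real_),
    mate_end = ifelse(is_tra, pos2, NA_real_))
  sort_sv_records(rec)
}

#' Write SV records in the Breakdancer-style tab-separated layout
#'
#' @param records [sv_records()] table (caller `breakdancer`).
#' @param path output file path.
#' @param libraries optional character vector (parallel to records) of
#'   `lib:count` lists; defaults to `n_libraries` synthetic library names
#'   splitting `n_read_pairs`.
#' @export
write_breakdancer_tsv <- function(records, path, libraries = NULL) {
  records <- sort_sv_records(records)
  if (nrow(records) == 0) { writeLines(character(0), path); return(invisible(path)) }
  if (is.null(libraries)) {
    libraries <- vapply(seq_len(nrow(records)), function(i) {
      k <- max(1L, records$n_libraries[i])
      per <- diff(round(seq(0, records$n_read_pairs[i], length.out = k + 1)))
      paste(sprintf("lib%02d:%d", seq_len(k), per), collapse = "|")
    }, "")
  }
  is_ins <- records$sv_class == "INS"
  is_tra <- records$sv_class == "TRA"
  type <- ifelse(is_tra, "CTX", records$sv_class)
  chrom2 <- ifelse(is_tra, records$mate_contig, records$contig)
  pos2 <- ifelse(is_tra, records$mate_end, records$end)
  size <- ifelse(is_ins, records$insertion_length, records$end - records$start)
  lines <- paste(records$contig,
                 format(records$start + 1, scientific = FALSE, trim = TRUE),
                 chrom2, format(pos2, scientific = FALSE, trim = TRUE),
                 type, format(size, scientific = FALSE, trim = TRUE),
                 format(records$score, scientific = FALSE, trim = TRUE),
                 records$n_read_pairs, libraries, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write consensus SVs as a 6-column BED file
#'
#' Columns: contig, start, end, consensus_id, number of species sharing the
#' event, SV class. Tab-separated, no header.
#'
#' @param svs [consensus_svs()] table (sorted).
#' @param path output file path.
#' @export
write_sv_bed <- function(svs, path) {
  if (nrow(svs) == 0) { writeLines(character(0), path); return(invisible(path)) }
  lines <- paste(svs$contig,
                 format(svs$start, scientific = FALSE, trim = TRUE),
                 format(svs$end, scientific = FALSE, trim = TRUE),
                 svs$consensus_id, n_species_of(svs), svs$sv_class, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 6-column SV BED file written by [write_sv_bed()]
#'
#' @param path BED file path.
#' @return data.frame with columns contig, start, end, consensus_id,
#'   n_species, sv_class.
#' @export
read_sv_bed <- function(path) {
  cols <- c("contig", "start", "end", "consensus_id", "n_species", "sv_class")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      consensus_id = character(), n_species = integer(),
                      sv_class = character(), stringsAsFactors = FALSE)
    return(out)
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "integer", "character"),
                          stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
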