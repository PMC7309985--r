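#' Size-conditional reciprocal-overlap thresholds for cross-species merging
#'
#' Events of different sizes tolerate different amounts of breakpoint
#' noise, so cross-species merging uses a size-dependent reciprocal-overlap
#' threshold. Default bands (bottom value included, top excluded): up to
#' 0.5 kb at 50%, 0.5-1 kb at 80%, 1-10 kb at 90%, and 10 kb or larger at
#' 95%. When the two events of a pair fall into different bands, the
#' stricter threshold governs.
#'
#' @param bands data.frame with columns `lower` (inclusive, nt), `upper`
#'   (exclusive, nt) and `threshold` (fraction); must partition `[0, Inf)`
#'   with non-decreasing thresholds.
#' @return a list of class `size_band_policy`.
#' @export
size_band_policy <- function(bands = data.frame(
  lower = c(0, 500, 1000, 10000),
  upper = c(500, 1000, 10000, Inf),
  threshold = c(0.50, 0.80, 0.90, 0.95))) {
  bands <- bands[order(bands$lower), , drop = FALSE]
  if (bands$lower[1] != 0 || !all(bands$upper[-nrow(bands)] == bands$lower[-1]) ||
      is.finite(bands$upper[nrow(bands)]))
    stop("bands must partition [0, Inf)")
  if (is.unsorted(bands$threshold))
    stop("band thresholds must be non-decreasing with size")
  p <- list(bands = bands)
  class(p) <- "size_band_policy"
  p
}

#' Threshold applicable to an event of a given size
#'
#' @param policy a [size_band_policy()].
#' @param len event length(s) in nt.
#' @return reciprocal-overlap threshold fraction(s).
#' @export
band_threshold <- function(policy, len) {
  idx <- findInterval(len, policy$bands$lower)
  policy$bands$threshold[idx]
}

#' Merge per-species consensus sets into multi-species events
#'
#' Single-linkage clustering of one SV class across species where an edge
#' between two events requires reciprocal overlap of at least the stricter
#' of their two size-band thresholds. Breakpoint classes use window
#' matching instead (`ins_window`/`tra_window` of the merge policy). Each
#' cluster becomes one consensus event whose representative interval is
#' the member with the highest total caller support (ties towards the
#' leftmost) and whose species set is the union over members.
#'
#' @param per_species named list mapping species to its final consensus
#'   [sv_records()] for one SV class.
#' @param policy a [size_band_policy()].
#' @param merge_pol a [merge_policy()] supplying the breakpoint windows.
#' @return a [consensus_svs()] table sorted by coordinates.
#' @export
conditional_merge_across_species <- function(per_species,
                                             policy = size_band_policy(),
                                             merge_pol = merge_policy()) {
  per_species <- per_species[order(names(per_species))]
  per_species <- per_species[vapply(per_species, nrow, 1L) > 0]
  if (!length(per_species)) {
    return(consensus_svs(character(), numeric(), numeric(), character(),
                         character(), character(), character(), character()))
  }
  df <- do.call(rbind_sv, unname(per_species))
  if (length(unique(df$sv_class)) > 1)
    stop("conditional_merge_across_species takes one SV class at a time")
  cls <- df$sv_class[1]
  df <- sort_sv_records(df)
  lens <- df$end - df$start
  thr_fun <- function(i, j) pmax(band_threshold(policy, lens[i]),
                                 band_threshold(policy, lens[j]))
  edges <- class_edges(df, cls, thr_fun, merge_pol$ins_window,
                       merge_pol$tra_window)
  comp <- components_from_edges(nrow(df), edges)
  rows <- lapply(unname(split(seq_len(nrow(df)), comp)), function(cl) {
    rep_i <- pick_representative(df, cl, merge_pol$representative_rule)
    sp <- sort(unique(df$species[cl]))
    cbs <- vapply(sp, function(s)
      paste0(s, "=", join_unique(rec_callers(df)[cl][df$species[cl] == s])), "")
    data.frame(contig = df$contig[rep_i], start = df$start[rep_i],
               end = df$end[rep_i], sv_class = cls,
               species_present = paste(sp, collapse = ";"),
               callers_by_species = paste(cbs, collapse = ";"),
               source_records = join_unique(rec_sources(df)[cl]),
               support = sum(rec_support(df)[cl]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  out$consensus_id <- sprintf("%s_%06d", cls, seq_len(nrow(out)))
  rownames(out) <- NULL
  consensus_svs(out$contig, out$start, out$end, out$sv_class,
                out$species_present, out$callers_by_species,
                out$source_records, out$consensus_id, out$support)
}

rbind_sv <- function(...) {
  sets <- list(...)
  sets <- lapply(sets, function(x) {
    for (col in c("callers", "support", "source_records")) {
      if (!col %in% names(x))
        x[[col]] <- switch(col, callers = x$caller, support = x$n_read_pairs,
                           source_records = x$record_id)
    }
    x
  })
  do.call(rbind, sets)
}

#' Classify events by the number of species sharing them
#'
#' An event present in every analyzed species is "conserved".
#'
#' @param svs [consensus_svs()] table.
#' @param all_species character vector of all analyzed species.
#' @return data.frame with `consensus_id`, `n_species`, `conserved`.
#' @export
classify_conservation <- function(svs, all_species) {
  sp <- strsplit(svs$species_present, ";", fixed = TRUE)
  unknown <- setdiff(unique(unlist(sp)), all_species)
  if (length(unknown))
    stop("species not in the analyzed set: ", paste(unknown, collapse = ", "))
  n <- lengths(sp)
  data.frame(consensus_id = svs$consensus_id, n_species = n,
             conserved = n == length(all_species), stringsAsFactors = FALSE)
}

#' Per-class conservation summary (Total / more than one species / all
#' species)
#'
#' @inheritParams classify_conservation
#' @return data.frame with one row per SV class and columns `total`,
#'   `multi_species`, `all_species`.
#' @export
conservation_table <- function(svs, all_species) {
  cc <- classify_conservation(svs, all_species)
  out <- do.call(rbind, lapply(sort(unique(svs$sv_class)), function(cls) {
    sel <- svs$sv_class == cls
    data.frame(sv_class = cls, total = sum(sel),
               multi_species = sum(sel & cc$n_species > 1),
               all_species = sum(sel & cc$conserved),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(sv_class = character(), total = integer(),
                      multi_species = integer(), all_species = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Mann-Whitney tests of event size against conservation level
#'
#' For each SV class and each pair of conservation levels (number of
#' species sharing the event), compares event sizes with a two-sided
#' Mann-Whitney rank test and reports the U statistic, the p-value and a
#' direction label (`"a < b"` meaning events at the lower conservation
#' level tend to be smaller). Pairs with fewer than 2 events in either
#' category are marked untestable.
#'
#' @param svs [consensus_svs()] table.
#' @param all_species character vector of analyzed species (defines the
#'   conservation levels).
#' @return data.frame with one row per class and level pair.
#' @export
size_by_conservation_tests <- function(svs, all_species) {
  cc <- classify_conservation(svs, all_species)
  sizes <- svs$end - svs$start
  rows <- list()
  for (cls in sort(unique(svs$sv_class))) {
    if (cls %in% c("INS", "TRA")) next  # breakpoint classes carry no span size
    sel <- svs$sv_class == cls
    levels_present <- sort(unique(cc$n_species[sel]))
    if (length(levels_present) < 2) next
    for (ai in seq_along(levels_present)[-length(levels_present)]) {
      for (bi in seq((ai + 1), length(levels_present))) {
        a <- levels_present[ai]; b <- levels_present[bi]
        xa <- sizes[sel & cc$n_species == a]
        xb <- sizes[sel & cc$n_species == b]
        if (length(xa) < 2 || length(xb) < 2) {
          rows[[length(rows) + 1]] <- data.frame(
            sv_class = cls, level_a = a, level_b = b,
            n_a = length(xa), n_b = length(xb), U = NA_real_, p = NA_real_,
            direction = "", untestable = TRUE, stringsAsFactors = FALSE)
          next
        }
        if (length(unique(c(xa, xb))) == 1) {
          # fully tied samples: no evidence of a shift in either direction
          wt <- list(statistic = length(xa) * length(xb) / 2, p.value = 1)
        } else {
          wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
        }
        u <- unname(wt$statistic)
        dir_label <- if (u < length(xa) * length(xb) / 2) {
          sprintf("%d < %d", a, b)
        } else if (u > length(xa) * length(xb) / 2) {
          sprintf("%d > %d", a, b)
        } else ""
        rows[[length(rows) + 1]] <- data.frame(
          sv_class = cls, level_a = a, level_b = b,
          n_a = length(xa), n_b = length(xb), U = u, p = wt$p.value,
          direction = dir_label, untestable = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sv_class = character(), level_a = integer(),
                      level_b = integer(), n_a = integer(), n_b = integer(),
                      U = numeric(), p = numeric(), direction = character(),
                      untestable = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
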