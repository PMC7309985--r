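#' Merge policy for within-tool and two-tool consensus building
#'
#' Span classes (DEL/DUP/INV) are merged when their reciprocal overlap
#' reaches the threshold (default 90% both within one tool and between two
#' tools). Reciprocal overlap is undefined for breakpoint classes:
#' insertions are matched when their breakpoints fall within `ins_window`
#' nt of each other, and translocations when both breakpoints fall within
#' `tra_window` nt of the partner call; translocations are exempt from
#' within-tool merging.
#'
#' @param within_tool_threshold reciprocal-overlap threshold for merging
#'   calls of one tool (default 0.90).
#' @param cross_tool_threshold reciprocal-overlap threshold for two-tool
#'   consensus (default 0.90).
#' @param classes_excluded_from_merge SV classes exempt from within-tool
#'   merging (default `"TRA"`).
#' @param representative_rule `"highest_support"` (default) or
#'   `"leftmost"`: how a merged cluster's representative coordinates are
#'   chosen.
#' @param ins_window insertion breakpoint matching window in nt
#'   (default 100).
#' @param tra_window translocation breakpoint matching window in nt
#'   (default 1000).
#' @return a list of class `merge_policy`.
#' @export
merge_policy <- function(within_tool_threshold = 0.90,
                         cross_tool_threshold = 0.90,
                         classes_excluded_from_merge = "TRA",
                         representative_rule = c("highest_support", "leftmost"),
                         ins_window = 100L, tra_window = 1000L) {
  if (within_tool_threshold <= 0 || within_tool_threshold > 1 ||
      cross_tool_threshold <= 0 || cross_tool_threshold > 1)
    stop("merge thresholds must lie in (0, 1]")
  p <- list(within_tool_threshold = within_tool_threshold,
            cross_tool_threshold = cross_tool_threshold,
            classes_excluded_from_merge = classes_excluded_from_merge,
            representative_rule = match.arg(representative_rule),
            ins_window = as.numeric(ins_window),
            tra_window = as.numeric(tra_window))
  class(p) <- "merge_policy"
  p
}

rec_callers <- function(df) {
  if ("callers" %in% names(df)) df$callers else df$caller
}

rec_sources <- function(df) {
  if ("source_records" %in% names(df)) df$source_records else df$record_id
}

rec_support <- function(df) {
  if ("support" %in% names(df)) df$support else df$n_read_pairs
}

join_unique <- function(...) {
  paste(sort(unique(unlist(strsplit(c(...), "|", fixed = TRUE)))),
        collapse = "|")
}

# all pairs (i, j), i < j in sorted order, whose starts/ends come within
# `gap` of touching on the same contig; returns a 2-column index matrix
candidate_pairs <- function(df, gap = 0) {
  n <- nrow(df)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ord <- order(df$contig, df$start, df$end)
  s <- df$start[ord]; e <- df$end[ord]; ctg <- df$contig[ord]
  ii <- integer(0); jj <- integer(0)
  active <- integer(0)
  for (k in seq_len(n)) {
    if (length(active)) {
      # input is sorted by (contig, start): stale contigs and intervals
      # ending at or before s[k] - gap can never pair with k or later rows
      active <- active[ctg[active] == ctg[k] & (e[active] + gap) > s[k]]
      if (length(active)) {
        ii <- c(ii, active); jj <- c(jj, rep.int(k, length(active)))
      }
    }
    active <- c(active, k)
  }
  cbind(ord[ii], ord[jj])
}

# union-find connected components over nrow(df) nodes given an edge index
# matrix; returns an integer component label per row
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

# edge predicate for one SV class under a merge/band threshold function
# thr_fun(i, j) returning the required reciprocal overlap per pair
class_edges <- function(df, sv_class, thr_fun, ins_window, tra_window) {
  if (sv_class == "INS" || sv_class == "TRA") {
    cand <- candidate_pairs(df, gap = if (sv_class == "INS") ins_window else tra_window)
    if (!nrow(cand)) return(cand)
    ok <- abs(df$start[cand[, 1]] - df$start[cand[, 2]]) <=
      (if (sv_class == "INS") ins_window else tra_window)
    if (sv_class == "TRA") {
      ok <- ok & !is.na(df$mate_contig[cand[, 1]]) &
        !is.na(df$mate_contig[cand[, 2]]) &
        df$mate_contig[cand[, 1]] == df$mate_contig[cand[, 2]] &
        abs(df$mate_start[cand[, 1]] - df$mate_start[cand[, 2]]) <= tra_window
    }
    return(cand[ok, , drop = FALSE])
  }
  cand <- candidate_pairs(df, gap = 0)
  if (!nrow(cand)) return(cand)
  ro <- ro_vec(df$start[cand[, 1]], df$end[cand[, 1]],
               df$start[cand[, 2]], df$end[cand[, 2]])
  ok <- ro >= thr_fun(cand[, 1], cand[, 2])
  cand[ok, , drop = FALSE]
}

# deterministic representative row index within a cluster
pick_representative <- function(df, idx, rule = "highest_support") {
  sup <- rec_support(df)[idx]
  key <- if (rule == "highest_support") {
    order(-sup, df$start[idx], df$end[idx], df$record_id[idx])
  } else {
    order(df$start[idx], df$end[idx], -sup, df$record_id[idx])
  }
  idx[key[1]]
}

merge_clusters <- function(df, comp, rule) {
  reps <- integer(0)
  srcs <- character(0)
  cals <- character(0)
  sups <- numeric(0)
  for (cl in split(seq_len(nrow(df)), comp)) {
    reps <- c(reps, pick_representative(df, cl, rule))
    srcs <- c(srcs, join_unique(rec_sources(df)[cl]))
    cals <- c(cals, join_unique(rec_callers(df)[cl]))
    sups <- c(sups, max(rec_support(df)[cl]))
  }
  out <- df[reps, , drop = FALSE]
  out$source_records <- srcs
  out$callers <- cals
  out$support <- sups
  sort_sv_records(out)
}

#' Collapse redundant calls of one tool by reciprocal overlap
#'
#' Single-linkage clusters calls whose pairwise reciprocal overlap reaches
#' `within_tool_threshold` and emits one representative record per cluster
#' (the member with highest read-pair support; ties broken by leftmost
#' start, then smallest end). Source record ids are preserved in the
#' `source_records` column. Classes listed in
#' `classes_excluded_from_merge` (translocations by default) pass through
#' unmerged; insertions are clustered by breakpoint proximity
#' (`ins_window`).
#'
#' @param records [sv_records()] from one species, one caller and one SV
#'   class.
#' @param policy a [merge_policy()].
#' @return merged [sv_records()] with `source_records`, `callers` and
#'   `support` columns.
#' @export
merge_within_tool <- function(records, policy = merge_policy()) {
  if (nrow(records) == 0) return(records)
  if (length(unique(records$sv_class)) > 1 ||
      length(unique(records$species)) > 1 ||
      length(unique(records$caller)) > 1)
    stop("merge_within_tool requires one species, one caller, one SV class")
  cls <- records$sv_class[1]
  records <- sort_sv_records(records)
  if (cls %in% policy$classes_excluded_from_merge) {
    records$source_records <- rec_sources(records)
    records$callers <- rec_callers(records)
    records$support <- rec_support(records)
    return(records)
  }
  thr <- policy$within_tool_threshold
  edges <- class_edges(records, cls, function(i, j) thr,
                       policy$ins_window, policy$tra_window)
  comp <- components_from_edges(nrow(records), edges)
  merge_clusters(records, comp, policy$representative_rule)
}

#' Two-tool consensus by greedy best-overlap matching
#'
#' Pairs records of two callers whose reciprocal overlap reaches
#' `cross_tool_threshold` (breakpoint-window matching for INS/TRA). Each
#' input record contributes to at most one output: candidate pairs are
#' taken greedily by decreasing overlap (ties towards the leftmost pair).
#' Each matched pair emits one record with the representative coordinates
#' and both callers annotated; unmatched records are dropped (two-tool
#' support is the definition of consensus).
#'
#' @param set_a,set_b within-tool merged [sv_records()] of the same species
#'   and SV class, from two different callers.
#' @param policy a [merge_policy()].
#' @return consensus [sv_records()] with `callers`, `support` and
#'   `source_records` columns.
#' @export
pairwise_consensus <- function(set_a, set_b, policy = merge_policy()) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty_consensus_records())
  if (length(unique(c(set_a$species, set_b$species))) > 1 ||
      length(unique(c(set_a$sv_class, set_b$sv_class))) > 1)
    stop("pairwise_consensus requires one species and one SV class")
  cls <- set_a$sv_class[1]
  df <- rbind_sv(set_a, set_b)
  grp <- rep(c(1L, 2L), c(nrow(set_a), nrow(set_b)))
  thr <- policy$cross_tool_threshold
  edges <- class_edges(df, cls, function(i, j) thr,
                       policy$ins_window, policy$tra_window)
  if (nrow(edges)) {
    cross <- grp[edges[, 1]] != grp[edges[, 2]]
    edges <- edges[cross, , drop = FALSE]
  }
  if (!nrow(edges)) return(empty_consensus_records())
  score <- if (cls %in% c("INS", "TRA")) {
    -abs(df$start[edges[, 1]] - df$start[edges[, 2]])
  } else {
    ro_vec(df$start[edges[, 1]], df$end[edges[, 1]],
           df$start[edges[, 2]], df$end[edges[, 2]])
  }
  ord <- order(-score,
               pmin(df$start[edges[, 1]], df$start[edges[, 2]]),
               df$record_id[edges[, 1]], df$record_id[edges[, 2]])
  used <- rep(FALSE, nrow(df))
  picked <- integer(0)
  for (r in ord) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (!used[i] && !used[j]) { used[i] <- used[j] <- TRUE; picked <- c(picked, r) }
  }
  rows <- lapply(picked, function(r) {
    pair <- c(edges[r, 1], edges[r, 2])
    rep_i <- pick_representative(df, pair, policy$representative_rule)
    out <- df[rep_i, , drop = FALSE]
    out$callers <- join_unique(rec_callers(df)[pair])
    out$source_records <- join_unique(rec_sources(df)[pair])
    out$support <- sum(rec_support(df)[pair])
    out
  })
  sort_sv_records(do.call(rbind, rows))
}

empty_consensus_records <- function() {
  out <- empty_sv_records()
  out$callers <- character(0)
  out$support <- numeric(0)
  out$source_records <- character(0)
  out
}

#' Build the species/class consensus set supported by at least two callers
#'
#' Takes the union of all pairwise two-tool consensus sets (e.g.
#' Breakdancer+Delly, Breakdancer+Pindel, Delly+Pindel), then deduplicates
#' events recovered by more than one pair with a final single-linkage pass
#' at `cross_tool_threshold`, merging caller provenance.
#'
#' @param by_caller named list mapping caller to its filtered, within-tool
#'   merged [sv_records()]; at least two callers required.
#' @param policy a [merge_policy()].
#' @return consensus [sv_records()] for the species/class.
#' @export
build_consensus_set <- function(by_caller, policy = merge_policy()) {
  if (length(by_caller) < 2)
    stop("build_consensus_set requires at least two callers")
  callers <- sort(names(by_caller))
  pairs <- utils::combn(callers, 2, simplify = FALSE)
  sets <- lapply(pairs, function(p)
    pairwise_consensus(by_caller[[p[1]]], by_caller[[p[2]]], policy))
  pooled <- do.call(rbind, sets)
  if (is.null(pooled) || nrow(pooled) == 0) return(empty_consensus_records())
  pooled$record_id_orig <- pooled$record_id
  pooled$record_id <- sprintf("u%06d", seq_len(nrow(pooled)))
  cls <- pooled$sv_class[1]
  pooled <- sort_sv_records(pooled)
  thr <- policy$cross_tool_threshold
  edges <- class_edges(pooled, cls, function(i, j) thr,
                       policy$ins_window, policy$tra_window)
  comp <- components_from_edges(nrow(pooled), edges)
  out <- merge_clusters(pooled, comp, policy$representative_rule)
  out$record_id <- out$record_id_orig
  out$record_id_orig <- NULL
  rownames(out) <- NULL
  out
}
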