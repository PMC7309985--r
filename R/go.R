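#' Build a GO DAG with propagated gene annotations
#'
#' The DAG is given as a child -> parent edge list (`is_a` relations only)
#' plus a gene -> term table of direct annotations. Annotations are
#' propagated upwards: every gene annotated to a term is annotated to all
#' of the term's ancestors, so the root annotates every annotated gene.
#' Term depth is the length of the longest path to a root, used to process
#' the most specific terms first in the elim algorithm.
#'
#' @param edges data.frame with columns `child`, `parent`.
#' @param gene2term data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return a list of class `go_dag` with elements `terms`, `parents`,
#'   `ancestors`, `direct`, `genes` (propagated gene sets) and `depth`.
#' @export
go_dag <- function(edges, gene2term) {
  terms <- sort(unique(c(edges$child, edges$parent, gene2term$term)))
  parents <- lapply(stats::setNames(terms, terms), function(t)
    sort(unique(edges$parent[edges$child == t])))
  # acyclicity (Kahn): repeatedly strip terms whose parents are all stripped
  remaining <- terms
  repeat {
    strippable <- remaining[vapply(parents[remaining], function(p)
      !any(p %in% remaining), TRUE)]
    if (!length(strippable)) break
    remaining <- setdiff(remaining, strippable)
  }
  if (length(remaining))
    stop("GO edge list contains a cycle involving: ",
         paste(utils::head(remaining, 5), collapse = ", "))

  depth <- stats::setNames(rep(NA_real_, length(terms)), terms)
  depth_of <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    d <- if (!length(parents[[t]])) 0 else
      1 + max(vapply(parents[[t]], depth_of, 1))
    depth[[t]] <<- d
    d
  }
  for (t in terms) depth_of(t)

  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  anc_of <- function(t) {
    if (!is.null(ancestors[[t]])) return(ancestors[[t]])
    a <- unique(c(parents[[t]],
                  unlist(lapply(parents[[t]], anc_of), use.names = FALSE)))
    ancestors[[t]] <<- sort(a)
    ancestors[[t]]
  }
  for (t in terms) anc_of(t)

  direct <- lapply(stats::setNames(terms, terms), function(t)
    sort(unique(gene2term$gene[gene2term$term == t])))
  genes <- direct
  for (t in terms) {
    for (a in ancestors[[t]]) genes[[a]] <- union(genes[[a]], direct[[t]])
  }
  genes <- lapply(genes, sort)

  dag <- list(terms = terms, parents = parents, ancestors = ancestors,
              direct = direct, genes = genes, depth = depth)
  class(dag) <- "go_dag"
  dag
}

#' Genes fully contained inside SV events
#'
#' A (gene, SV) pair is reported iff the gene interval is entirely covered
#' by the SV interval (the bedtools `-f 1` containment rule); genes
#' straddling an SV boundary are excluded. A gene may pair with several
#' SVs.
#'
#' @param genes data.frame with columns `contig`, `start`, `end`,
#'   `gene_id` (and optionally `mappable`).
#' @param svs [consensus_svs()] table (or any interval table with a
#'   `consensus_id` column).
#' @return data.frame with columns `gene_id`, `consensus_id`.
#' @export
genes_fully_inside <- function(genes, svs) {
  out <- list()
  for (ctg in intersect(unique(genes$contig), unique(svs$contig))) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    s <- svs[svs$contig == ctg, , drop = FALSE]
    for (r in seq_len(nrow(s))) {
      hit <- g$start >= s$start[r] & g$end <= s$end[r]
      if (any(hit))
        out[[length(out) + 1]] <- data.frame(gene_id = g$gene_id[hit],
                                             consensus_id = s$consensus_id[r],
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), consensus_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$consensus_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GO term enrichment with elim decorrelation
#'
#' Tests every sufficiently annotated term for over-representation of the
#' study genes with a one-sided Fisher's exact (hypergeometric upper-tail)
#' test, processing terms from the most specific (greatest depth, ties in
#' lexicographic order) to the root. When a term is significant at
#' `elim_cutoff`, its genes are removed from all ancestor terms' gene sets
#' before those are tested — the elim decorrelation of the GO hierarchy.
#' Reported `annotated`/`significant`/`expected` use the original
#' propagated annotation (classic counts); `p_elim` uses the current,
#' possibly reduced sets. With `elim_cutoff = 0` the procedure reduces to
#' the classic Fisher test on every term.
#'
#' @param study character vector of study gene ids (subset of `universe`).
#' @param universe character vector of background gene ids.
#' @param dag a [go_dag()].
#' @param elim_cutoff p-value below which a term's genes are eliminated
#'   from its ancestors (default 0.01).
#' @param node_size minimum number of annotated genes (within the
#'   universe) for a term to be tested (default 5).
#' @return data.frame with one row per tested term, sorted by `p_elim`.
#' @export
go_enrichment_elim <- function(study, universe, dag, elim_cutoff = 0.01,
                               node_size = 5L) {
  study <- unique(study); universe <- unique(universe)
  if (length(setdiff(study, universe)))
    stop("study genes absent from the universe: ",
         paste(utils::head(setdiff(study, universe), 5), collapse = ", "))
  orig <- lapply(dag$genes, intersect, y = universe)
  testable <- dag$terms[lengths(orig[dag$terms]) >= node_size]
  if (!length(testable))
    return(data.frame(term = character(), annotated = integer(),
                      significant = integer(), expected = numeric(),
                      p_elim = numeric(), stringsAsFactors = FALSE))
  ord <- testable[order(-dag$depth[testable], testable)]
  current <- orig
  n_univ <- length(universe)
  n_study <- length(study)
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    t <- ord[i]
    cur <- current[[t]]
    K <- length(cur)
    k <- length(intersect(cur, study))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, n_univ - K, n_study, lower.tail = FALSE)
    rows[[i]] <- data.frame(
      term = t,
      annotated = length(orig[[t]]),
      significant = length(intersect(orig[[t]], study)),
      expected = length(orig[[t]]) * n_study / n_univ,
      p_elim = p, stringsAsFactors = FALSE)
    if (p < elim_cutoff && length(cur)) {
      for (a in dag$ancestors[[t]]) current[[a]] <- setdiff(current[[a]], cur)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$p_elim, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
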