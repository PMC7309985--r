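#' Branch names of a rooted tree
#'
#' Every branch is identified by the clade it subtends: the sorted leaf
#' names joined with `+`. The root itself is treated as a (possibly
#' zero-information) branch subtending all leaves, so that events shared
#' by every species can be assigned a gain; its length is `tree$root.edge`
#' when the newick input carries one, otherwise `NA`.
#'
#' @param tree an [ape::read.tree()] `phylo` object (rooted, branch
#'   lengths in million years).
#' @return data.frame with `branch` (name), `node` (ape node index),
#'   `length` (MY) and `is_root`.
#' @export
tree_branches <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  nodes <- c(seq_len(n_tip), seq_len(tree$Nnode) + n_tip)
  leafsets <- node_leafsets(tree)
  len <- rep(NA_real_, max(nodes))
  len[tree$edge[, 2]] <- tree$edge.length
  if (!is.null(tree$root.edge)) len[root] <- tree$root.edge
  data.frame(
    branch = vapply(nodes, function(nd) paste(sort(leafsets[[nd]]), collapse = "+"), ""),
    node = nodes,
    length = len[nodes],
    is_root = nodes == root,
    stringsAsFactors = FALSE)
}

# list indexed by ape node number -> character vector of descendant leaves
node_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # postorder: a node's subtree edges precede the edge into the node itself
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(post))) {
    parent <- post[r, 1]; child <- post[r, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

node_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(length(tree$tip.label) + tree$Nnode)))
}

#' Dollo-parsimony gain/loss reconstruction of one presence pattern
#'
#' Under Dollo parsimony the derived state (presence of the SV relative to
#' the reference) arises exactly once. The gain is placed on the branch
#' subtending the most recent common ancestor of the species carrying the
#' event; losses are placed on the branches subtending the maximal
#' subtrees below the gain that contain no carrier. The root state is
#' absence: an SV is defined relative to the reference genome, so presence
#' is the derived state (with the usual polarity caveat that a gain on the
#' root branch could equally be a change on the reference lineage).
#'
#' @param presence character vector of species carrying the event
#'   (non-empty subset of the tree's leaves).
#' @param tree rooted `phylo` tree.
#' @return list with `gain_branch` (branch name), `loss_branches`
#'   (character vector of branch names, possibly empty) and `retained`
#'   (`TRUE` when no losses are required).
#' @examples
#' tr <- ape::read.tree(text = "(((Mz:5,Pn:5):2.5,Hb:7.5):4.5,Nb:12);")
#' dollo_reconstruct(c("Mz", "Hb"), tr)
#' @export
dollo_reconstruct <- function(presence, tree) {
  presence <- unique(presence)
  if (!length(presence)) stop("presence set must be non-empty")
  unknown <- setdiff(presence, tree$tip.label)
  if (length(unknown))
    stop("presence contains unknown species: ", paste(unknown, collapse = ", "))
  n_tip <- length(tree$tip.label)
  leafsets <- node_leafsets(tree)
  children <- node_children(tree)
  mrca <- if (length(presence) == 1) {
    match(presence, tree$tip.label)
  } else {
    ape::getMRCA(tree, presence)
  }
  name_of <- function(nd) paste(sort(leafsets[[nd]]), collapse = "+")
  losses <- character(0)
  walk <- function(nd) {
    for (ch in children[[nd]]) {
      if (!any(leafsets[[ch]] %in% presence)) {
        losses <<- c(losses, name_of(ch))
      } else if (ch > n_tip) {
        walk(ch)
      }
    }
  }
  if (mrca > n_tip) walk(mrca)
  list(gain_branch = name_of(mrca),
       loss_branches = sort(losses),
       retained = length(losses) == 0)
}

#' Per-branch gain/loss summary and net gain rates
#'
#' Reconstructs every event with [dollo_reconstruct()] and tabulates per
#' branch: gains, losses, retained gains (gains with no subsequent loss
#' anywhere in the tree) and the net gain rate `(gains - losses) / branch
#' length` in events per million years. The rate is `NA` where the branch
#' length is missing or zero (notably the root branch when the newick
#' input has no root edge); `root_polarity_flag` marks root-branch gains,
#' whose polarity is ambiguous without an outgroup.
#'
#' @param svs [consensus_svs()] table (its `species_present` column
#'   defines the presence patterns), or a character vector of `;`-joined
#'   presence patterns.
#' @param tree rooted `phylo` tree with branch lengths in million years.
#' @return data.frame with one row per branch.
#' @export
per_branch_summary <- function(svs, tree) {
  patterns <- if (is.character(svs)) svs else svs$species_present
  br <- tree_branches(tree)
  gains <- stats::setNames(integer(nrow(br)), br$branch)
  losses <- gains
  retained <- gains
  for (p in patterns) {
    rec <- dollo_reconstruct(strsplit(p, ";", fixed = TRUE)[[1]], tree)
    gains[rec$gain_branch] <- gains[rec$gain_branch] + 1L
    if (length(rec$loss_branches))
      losses[rec$loss_branches] <- losses[rec$loss_branches] + 1L
    if (rec$retained)
      retained[rec$gain_branch] <- retained[rec$gain_branch] + 1L
  }
  net <- ifelse(!is.na(br$length) & br$length > 0,
                (gains - losses) / br$length, NA_real_)
  undefined <- is.na(net) & (gains + losses) > 0
  data.frame(branch = br$branch, length_my = br$length,
             gains = unname(gains), losses = unname(losses),
             retained_gains = unname(retained),
             net_gain_rate = unname(net),
             rate_undefined = unname(undefined),
             root_polarity_flag = unname(br$is_root & gains > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-event reconstruction table
#'
#' @inheritParams per_branch_summary
#' @return data.frame with `consensus_id`, `gain_branch`, `loss_branches`
#'   (`|`-joined) and `retained`.
#' @export
reconstruct_events <- function(svs, tree) {
  recs <- lapply(strsplit(svs$species_present, ";", fixed = TRUE),
                 dollo_reconstruct, tree = tree)
  data.frame(
    consensus_id = svs$consensus_id,
    sv_class = svs$sv_class,
    gain_branch = vapply(recs, `[[`, "", "gain_branch"),
    loss_branches = vapply(recs, function(r)
      paste(r$loss_branches, collapse = "|"), ""),
    retained = vapply(recs, `[[`, TRUE, "retained"),
    stringsAsFactors = FALSE)
}
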