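# Brute-force oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (per-nucleotide scans, exhaustive
# enumeration) and independent of the package's implementations.

radiation_tree <- function() {
  ape::read.tree(
    text = "(((Mzebra:5,Pnyererei:5):2.5,Hburtoni:7.5):4.5,Nbrichardi:12):6;")
}

make_records <- function(start, end, sv_class = "DEL", species = "sp1",
                         caller = "delly", n_read_pairs = 10L, ...) {
  sv_records(contig = "lg1", start = start, end = end, sv_class = sv_class,
             species = species, caller = caller,
             n_read_pairs = n_read_pairs, ...)
}

random_interval_records <- function(n, span = 1e5, len_range = c(50, 5000),
                                    species = "sp1", caller = "delly",
                                    sv_class = "DEL") {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  make_records(start, start + len, sv_class = sv_class, species = species,
               caller = caller,
               n_read_pairs = sample.int(50, n, replace = TRUE))
}

# components from a full boolean edge matrix by iterative minimum-label
# propagation (independent of the package's union-find)
oracle_components_from_matrix <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[i], comp[nb])
        if (m < comp[i] || any(comp[nb] > m)) {
          comp[i] <- m
          comp[nb] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# vectorized O(n^2) reciprocal-overlap matrix
oracle_ro_matrix <- function(df) {
  n <- nrow(df)
  inter <- pmax(0, outer(df$end, df$end, pmin) - outer(df$start, df$start, pmax))
  same_ctg <- outer(df$contig, df$contig, "==")
  len <- df$end - df$start
  ro <- pmin(inter / matrix(len, n, n), inter / matrix(len, n, n, byrow = TRUE))
  ro * same_ctg
}

# O(n^2) single-linkage components under an arbitrary edge predicate
oracle_components <- function(df, edge_fun) {
  n <- nrow(df)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (edge_fun(i, j)) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  comp
}

oracle_ro <- function(df, i, j) {
  if (df$contig[i] != df$contig[j]) return(0)
  inter <- max(0, min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]))
  min(inter / (df$end[i] - df$start[i]), inter / (df$end[j] - df$start[j]))
}

# canonical partition signature, invariant to label permutations
partition_signature <- function(comp, key) {
  groups <- split(key, comp)
  sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
}

# exhaustive minimal single-gain Dollo scenario via bitmask enumeration:
# every branch as gain, every subset of branches strictly below it as
# losses; returns the scenario with fewest losses reproducing `presence`
oracle_dollo <- function(presence, tree) {
  br <- svlineage::tree_branches(tree)
  tips <- tree$tip.label
  mask_of <- function(leaves) sum(2^(match(leaves, tips) - 1))
  branch_leaves <- strsplit(br$branch, "+", fixed = TRUE)
  branch_mask <- vapply(branch_leaves, mask_of, 1)
  target <- mask_of(presence)
  best <- NULL
  for (gi in seq_len(nrow(br))) {
    below <- which(bitwAnd(branch_mask, branch_mask[gi]) == branch_mask &
                     branch_mask < branch_mask[gi])
    k <- length(below)
    for (s in 0:(2^k - 1)) {
      loss_idx <- below[bitwAnd(s, 2^(seq_len(k) - 1)) > 0]
      lost <- if (length(loss_idx)) Reduce(bitwOr, branch_mask[loss_idx]) else 0
      implied <- bitwAnd(branch_mask[gi], bitwNot(lost))
      if (implied == target) {
        n_loss <- length(loss_idx)
        if (is.null(best) || n_loss < best$n_loss)
          best <- list(gain = br$branch[gi], n_loss = n_loss)
      }
    }
  }
  best
}

# direct hypergeometric upper tail by summation of choose() terms
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# per-nucleotide overlap count between two interval sets
oracle_overlap_nt <- function(a, b, span = 2000) {
  tot <- 0
  for (ctg in union(a$contig, b$contig)) {
    pos <- seq_len(span) - 1
    ina <- rep(FALSE, span); inb <- rep(FALSE, span)
    aa <- a[a$contig == ctg, , drop = FALSE]
    bb <- b[b$contig == ctg, , drop = FALSE]
    for (r in seq_len(nrow(aa))) ina[pos >= aa$start[r] & pos < aa$end[r]] <- TRUE
    for (r in seq_len(nrow(bb))) inb[pos >= bb$start[r] & pos < bb$end[r]] <- TRUE
    tot <- tot + sum(ina & inb)
  }
  tot
}

noisy_profiles <- function() {
  p <- list(sensitivity = 0.95, fp_per_mb = 0.5, jitter_sd = 50)
  list(breakdancer = p, delly = p, pindel = p)
}

# run filter -> within-tool merge -> two-tool consensus -> deletion floor
# -> cross-species merge for a simulated truth set
run_consensus_pipeline <- function(sim, truth, seed_base = 100L) {
  species <- sort(sim$tree$tip.label)
  cbs <- list()
  for (si in seq_along(species)) {
    calls <- simulate_caller_calls(truth, species[si], sim,
                                   seed = seed_base + si)
    cons <- species_consensus(calls)
    if (!is.null(cons$DEL)) cons$DEL <- filter_deletion_size(cons$DEL)
    cbs[[species[si]]] <- cons
  }
  cross_species_stage(cbs)
}
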