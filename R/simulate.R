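#' Configuration of the synthetic SV-evolution simulator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: single-origin (Dollo) gains placed on tree branches
#' at branch-length-proportional Poisson rates, whole-event losses on
#' descendant branches, class-specific log-normal size distributions, and
#' per-caller detection noise (sensitivity, breakpoint jitter, false
#' positives, support/score metadata). Defaults describe a four-species
#' East African cichlid radiation mapped to a common reference: divergence
#' times of 5 MY (Mzebra/Pnyererei), 7.5 MY (+Hburtoni) and 12 MY
#' (Nbrichardi), with a 6 MY stem (root) branch on which events shared by
#' all four species arise. Deletion sizes are drawn above a 1 kb floor
#' with ~18% of events above 10 kb, matching the size spectrum read-pair
#' callers retain after small-deletion filtering.
#'
#' @param tree_newick rooted newick with branch lengths in MY; a trailing
#'   root edge length gives the stem branch.
#' @param genome data.frame with columns `contig`, `length`.
#' @param gain_rate named numeric, events per MY per SV class.
#' @param loss_rate events per MY at which an existing event flips to
#'   absent on a descendant branch.
#' @param size_dist named list per class: `c(meanlog, sdlog, min)` for the
#'   event length (INS: inserted length) in nt.
#' @param caller_profiles named list per caller with `sensitivity`,
#'   `fp_per_mb`, `jitter_sd`.
#' @param n_repeats,repeat_len_meanlog,repeat_len_sdlog repeat annotation
#'   size/count parameters.
#' @param repeat_boost_class,repeat_boost_factor repeat class planted at
#'   `repeat_boost_factor` times the genome-average density inside true
#'   inversion regions — the fold change a permutation enrichment test of
#'   inversions against that class recovers.
#' @param n_genes,gene_len_meanlog,gene_len_sdlog gene annotation
#'   parameters; `prop_mappable` is the fraction of genes carrying a
#'   cross-reference id (the GO universe).
#' @param seed integer; fixes all downstream randomness.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    tree_newick = "(((Mzebra:5,Pnyererei:5):2.5,Hburtoni:7.5):4.5,Nbrichardi:12):6;",
    genome = data.frame(contig = paste0("lg", 1:5), length = 1e7),
    gain_rate = c(DEL = 22, DUP = 8, INV = 9, INS = 6, TRA = 3),
    loss_rate = 0.01,
    size_dist = list(DEL = c(meanlog = 8.3, sdlog = 1.0, min = 1000),
                     DUP = c(meanlog = 8.6, sdlog = 1.1, min = 300),
                     INV = c(meanlog = 8.6, sdlog = 1.1, min = 300),
                     INS = c(meanlog = 5.7, sdlog = 0.8, min = 50),
                     TRA = c(meanlog = 0, sdlog = 0, min = 1)),
    caller_profiles = list(
      breakdancer = list(sensitivity = 1, fp_per_mb = 0, jitter_sd = 0),
      delly = list(sensitivity = 1, fp_per_mb = 0, jitter_sd = 0),
      pindel = list(sensitivity = 1, fp_per_mb = 0, jitter_sd = 0)),
    n_repeats = 4000, repeat_len_meanlog = 5.5, repeat_len_sdlog = 0.5,
    repeat_boost_class = "SINE", repeat_boost_factor = 3,
    n_genes = 1200, gene_len_meanlog = 7.6, gene_len_sdlog = 0.5,
    prop_mappable = 0.9,
    seed = 1L) {
  stopifnot(all(gain_rate >= 0), loss_rate >= 0,
            all(vapply(caller_profiles, function(p)
              p$sensitivity >= 0 && p$sensitivity <= 1, TRUE)))
  cfg <- list(tree_newick = tree_newick, genome = genome,
              gain_rate = gain_rate, loss_rate = loss_rate,
              size_dist = size_dist, caller_profiles = caller_profiles,
              n_repeats = n_repeats,
              repeat_len_meanlog = repeat_len_meanlog,
              repeat_len_sdlog = repeat_len_sdlog,
              repeat_boost_class = repeat_boost_class,
              repeat_boost_factor = repeat_boost_factor,
              n_genes = n_genes, gene_len_meanlog = gene_len_meanlog,
              gene_len_sdlog = gene_len_sdlog,
              prop_mappable = prop_mappable,
              seed = as.integer(seed))
  cfg$tree <- ape::read.tree(text = tree_newick)
  class(cfg) <- "simulation_config"
  cfg
}

rlnorm_min <- function(n, meanlog, sdlog, min) {
  if (n == 0) return(numeric(0))
  x <- round(stats::rlnorm(n, meanlog, sdlog))
  bad <- which(x < min)
  tries <- 0
  while (length(bad) && tries < 100) {
    x[bad] <- round(stats::rlnorm(length(bad), meanlog, sdlog))
    bad <- bad[x[bad] < min]
    tries <- tries + 1
  }
  x[x < min] <- min
  x
}

# place n non-overlapping intervals of the given sizes on the genome;
# rejection sampling against previously accepted intervals
place_nonoverlapping <- function(sizes, genome, max_rounds = 60) {
  n <- length(sizes)
  contig <- character(n); start <- numeric(n)
  placed <- rep(FALSE, n)
  occ <- lapply(stats::setNames(genome$contig, genome$contig),
                function(x) data.frame(start = numeric(0), end = numeric(0)))
  probs <- genome$length / sum(genome$length)
  round_i <- 0
  while (any(!placed) && round_i < max_rounds) {
    round_i <- round_i + 1
    todo <- which(!placed)
    todo <- todo[order(-sizes[todo])]  # large events first: they need the room
    ctg_i <- sample.int(nrow(genome), length(todo), replace = TRUE, prob = probs)
    pos <- floor(stats::runif(length(todo)) *
                   pmax(1, genome$length[ctg_i] - sizes[todo]))
    ok <- sizes[todo] <= genome$length[ctg_i]
    # accept sequentially against the occupancy map
    for (k in seq_along(todo)) {
      if (!ok[k]) next
      ctg <- genome$contig[ctg_i[k]]
      s <- pos[k]; e <- pos[k] + sizes[todo[k]]
      o <- occ[[ctg]]
      if (nrow(o) && any(o$end > s & o$start < e)) next
      occ[[ctg]] <- rbind(o, data.frame(start = s, end = e))
      contig[todo[k]] <- ctg; start[todo[k]] <- s; placed[todo[k]] <- TRUE
    }
  }
  if (any(!placed))
    stop("genome too small to place ", sum(!placed),
         " events without overlap")
  data.frame(contig = contig, start = start, end = start + sizes,
             stringsAsFactors = FALSE)
}

# descendant branches of `node`, flipping state with per-branch Poisson
# probability; returns surviving leaves and the branches where flips occur
thin_losses <- function(tree, node, loss_rate, leafsets, children, lens) {
  n_tip <- length(tree$tip.label)
  lost_branches <- character(0)
  surviving <- character(0)
  descend <- function(nd) {
    if (nd <= n_tip) { surviving <<- c(surviving, tree$tip.label[nd]); return() }
    for (ch in children[[nd]]) {
      p_flip <- 1 - exp(-loss_rate * lens[ch])
      if (stats::runif(1) < p_flip) {
        lost_branches <- c(lost_branches,
                           paste(sort(leafsets[[ch]]), collapse = "+"))
        lost_branches <<- lost_branches
      } else {
        descend(ch)
      }
    }
  }
  descend(node)
  list(surviving = surviving, lost = lost_branches)
}

#' Simulate SV gain/loss evolution along the tree
#'
#' Per branch and SV class, gains arise as Poisson counts proportional to
#' branch length; each gain receives a non-overlapping genomic interval
#' (within its class) and a class-specific log-normal size. Losses are
#' whole-event state flips on descendant branches (Poisson thinning, one
#' flip terminating descent). Events losing every descendant leaf are
#' unobservable and dropped. The recorded gain/loss branches are the
#' Dollo-minimal representation of the resulting leaf presence pattern —
#' the only representation identifiable from leaf data.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame of truth events: `event_id`, interval columns,
#'   `sv_class`, `insertion_length`, mate columns, `species_present`
#'   (`;`-joined), `gain_branch`, `loss_branches` (`|`-joined),
#'   `retained`.
#' @export
simulate_sv_evolution <- function(cfg) {
  set.seed(cfg$seed)
  tree <- cfg$tree
  br <- tree_branches(tree)
  leafsets <- node_leafsets(tree)
  children <- node_children(tree)
  lens <- rep(NA_real_, max(br$node))
  lens[br$node] <- br$length
  rows <- list()
  for (cls in names(cfg$gain_rate)) {
    rate <- cfg$gain_rate[[cls]]
    if (rate == 0) next
    sd <- cfg$size_dist[[cls]]
    for (bi in seq_len(nrow(br))) {
      blen <- br$length[bi]
      if (is.na(blen) || blen <= 0) next
      n_gain <- stats::rpois(1, rate * blen)
      if (n_gain == 0) next
      for (g in seq_len(n_gain)) {
        node <- br$node[bi]
        th <- thin_losses(tree, node, cfg$loss_rate, leafsets, children, lens)
        if (!length(th$surviving)) next  # extinct, unobservable
        rec <- dollo_reconstruct(th$surviving, tree)
        rows[[length(rows) + 1]] <- data.frame(
          sv_class = cls,
          size = NA_real_,
          species_present = paste(sort(th$surviving), collapse = ";"),
          gain_branch = rec$gain_branch,
          loss_branches = paste(rec$loss_branches, collapse = "|"),
          retained = rec$retained,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(event_id = character(), contig = character(),
                      start = numeric(), end = numeric(),
                      sv_class = character(), insertion_length = integer(),
                      mate_contig = character(), mate_start = numeric(),
                      mate_end = numeric(), species_present = character(),
                      gain_branch = character(), loss_branches = character(),
                      retained = logical(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows)
  # intervals: spans for DEL/DUP/INV, 1-nt breakpoints for INS/TRA
  out <- list()
  for (cls in unique(ev$sv_class)) {
    sub <- ev[ev$sv_class == cls, , drop = FALSE]
    sd <- cfg$size_dist[[cls]]
    if (cls %in% c("INS", "TRA")) {
      span <- rep(1, nrow(sub))
    } else {
      span <- rlnorm_min(nrow(sub), sd[["meanlog"]], sd[["sdlog"]], sd[["min"]])
    }
    pl <- place_nonoverlapping(span, cfg$genome)
    sub$contig <- pl$contig; sub$start <- pl$start; sub$end <- pl$end
    sub$insertion_length <- if (cls == "INS") {
      as.integer(rlnorm_min(nrow(sub), sd[["meanlog"]], sd[["sdlog"]], sd[["min"]]))
    } else 0L
    if (cls == "TRA") {
      mate <- place_nonoverlapping(rep(1, nrow(sub)), cfg$genome)
      sub$mate_contig <- mate$contig
      sub$mate_start <- mate$start
      sub$mate_end <- mate$end
    } else {
      sub$mate_contig <- NA_character_
      sub$mate_start <- NA_real_
      sub$mate_end <- NA_real_
    }
    out[[cls]] <- sub
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$sv_class, ev$contig, ev$start), , drop = FALSE]
  ev$event_id <- sprintf("truth_%s_%05d", ev$sv_class,
                         as.integer(stats::ave(seq_len(nrow(ev)), ev$sv_class,
                                               FUN = seq_along)))
  rownames(ev) <- NULL
  ev[, c("event_id", "contig", "start", "end", "sv_class",
         "insertion_length", "mate_contig", "mate_start", "mate_end",
         "species_present", "gain_branch", "loss_branches", "retained")]
}

jitter_clamp <- function(pos, sd, lo, hi) {
  if (sd > 0) pos <- pos + round(stats::rnorm(length(pos), 0, sd))
  pmin(pmax(pos, lo), hi)
}

#' Simulate one species' multi-caller SV call sets from the truth
#'
#' Each truth event carried by the species is emitted by each caller with
#' probability `sensitivity`; breakpoints are perturbed by rounded normal
#' jitter (sd `jitter_sd` nt, clamped within the contig). Support counts
#' and scores of true calls are drawn so that the default
#' [filter_thresholds()] keep them. False positives are added as
#' `Poisson(fp_per_mb x genome Mb)` random events with partly
#' sub-threshold support.
#'
#' @param truth data.frame from [simulate_sv_evolution()].
#' @param species leaf name.
#' @param cfg a [simulation_config()] (supplies genome and caller
#'   profiles).
#' @param seed integer seed for this species' call generation.
#' @return named list mapping caller to its [sv_records()].
#' @export
simulate_caller_calls <- function(truth, species, cfg, seed) {
  set.seed(seed)
  clens <- stats::setNames(cfg$genome$length, cfg$genome$contig)
  present <- truth[vapply(strsplit(truth$species_present, ";", fixed = TRUE),
                          function(s) species %in% s, TRUE), , drop = FALSE]
  out <- list()
  for (caller in names(cfg$caller_profiles)) {
    prof <- cfg$caller_profiles[[caller]]
    det <- present[stats::runif(nrow(present)) < prof$sensitivity, ,
                   drop = FALSE]
    n <- nrow(det)
    if (n) {
      is_bp <- det$sv_class %in% c("INS", "TRA")
      s <- jitter_clamp(det$start, prof$jitter_sd, 0, clens[det$contig] - 1)
      e <- ifelse(is_bp, s + 1,
                  jitter_clamp(det$end, prof$jitter_sd, 0, clens[det$contig]))
      # keep spans positive after jitter
      flip <- !is_bp & e <= s
      if (any(flip)) e[flip] <- s[flip] + 1
      true_rec <- sv_records(
        contig = det$contig, start = s, end = e, sv_class = det$sv_class,
        species = species, caller = caller,
        n_libraries = 2L + stats::rpois(n, 1),
        n_read_pairs = 5L + stats::rpois(n, 8),
        score = if (caller == "breakdancer") 99 else
          if (caller == "delly") round(stats::runif(n, 100, 999)) else NA_real_,
        filter_pass = TRUE, precise = TRUE,
        insertion_length = det$insertion_length,
        mate_contig = det$mate_contig,
        mate_start = det$mate_start, mate_end = det$mate_end,
        record_id = sprintf("%s_%s_t%05d", species, caller, seq_len(n)))
    } else true_rec <- empty_sv_records()

    n_fp <- stats::rpois(1, prof$fp_per_mb * sum(cfg$genome$length) / 1e6)
    if (n_fp > 0) {
      cls <- sample(names(cfg$gain_rate)[cfg$gain_rate > 0], n_fp,
                    replace = TRUE,
                    prob = cfg$gain_rate[cfg$gain_rate > 0])
      sizes <- vapply(cls, function(cl) {
        sd <- cfg$size_dist[[cl]]
        if (cl %in% c("INS", "TRA")) 1 else
          rlnorm_min(1, sd[["meanlog"]], sd[["sdlog"]], sd[["min"]])
      }, 1)
      ctg_i <- sample.int(nrow(cfg$genome), n_fp, replace = TRUE,
                          prob = cfg$genome$length)
      st <- floor(stats::runif(n_fp) * pmax(1, cfg$genome$length[ctg_i] - sizes))
      is_tra <- cls == "TRA"
      mate_i <- sample.int(nrow(cfg$genome), n_fp, replace = TRUE)
      mate_pos <- floor(stats::runif(n_fp) * (cfg$genome$length[mate_i] - 1))
      fp_rec <- sv_records(
        contig = cfg$genome$contig[ctg_i], start = st, end = st + sizes,
        sv_class = cls, species = species, caller = caller,
        n_libraries = 1L + stats::rpois(n_fp, 1),
        n_read_pairs = 2L + stats::rpois(n_fp, 5),
        score = if (caller == "breakdancer")
          sample(c(30:99), n_fp, replace = TRUE) else
            if (caller == "delly") round(stats::runif(n_fp, 50, 999)) else NA_real_,
        filter_pass = stats::runif(n_fp) < 0.7,
        precise = stats::runif(n_fp) < 0.7,
        insertion_length = ifelse(cls == "INS", 200L, 0L),
        mate_contig = ifelse(is_tra, cfg$genome$contig[mate_i], NA_character_),
        mate_start = ifelse(is_tra, mate_pos, NA_real_),
        mate_end = ifelse(is_tra, mate_pos + 1, NA_real_),
        record_id = sprintf("%s_%s_f%05d", species, caller, seq_len(n_fp)))
      rec <- rbind(true_rec, fp_rec)
      class(rec) <- class(true_rec)
    } else rec <- true_rec
    out[[caller]] <- sort_sv_records(rec)
  }
  out
}

#' Simulate annotation inputs: repeats, genes, GO, and alignments
#'
#' Repeats are placed with a `repeat_boost_factor` density boost of
#' `repeat_boost_class` elements inside the true inversion regions (a
#' planted, recoverable interval enrichment); genes are placed uniformly;
#' a small three-level GO DAG is built with one planted term
#' (`GO:PLANTED`) whose genes are drawn preferentially from genes inside
#' true inversions; per-species alignment block sets tile each reference
#' contig excluding that species' true deletions, so that
#' [deletion_concordance()] on the truth is 0% discordant while any
#' non-deleted interval is fully spanned by a block.
#'
#' @param cfg a [simulation_config()].
#' @param truth data.frame from [simulate_sv_evolution()].
#' @param seed integer seed.
#' @return list with `repeats`, `genes`, `go_edges`, `gene2term`,
#'   `alignments` (named list per species of [alignment_blocks()]).
#' @export
simulate_annotation <- function(cfg, truth, seed) {
  set.seed(seed)
  genome_iv <- genomic_intervals(cfg$genome$contig, 0, cfg$genome$length)
  inv <- truth[truth$sv_class == "INV", c("contig", "start", "end")]
  inv_u <- iv_union(inv)
  out_u <- iv_complement(inv_u, genome_iv)
  len_in <- iv_total_nt(inv_u)
  len_out <- iv_total_nt(out_u)

  # repeats ------------------------------------------------------------
  classes <- c(DNA = 0.40, LINE = 0.15, SINE = 0.18, LTR = 0.15,
               Simple_repeat = 0.06, Low_complexity = 0.04, Satellite = 0.02)
  cls <- sample(names(classes), cfg$n_repeats, replace = TRUE, prob = classes)
  lens <- rlnorm_min(cfg$n_repeats, cfg$repeat_len_meanlog,
                     cfg$repeat_len_sdlog, 30)
  boost <- cls == cfg$repeat_boost_class
  f <- len_in / (len_in + len_out)
  # repeat_boost_factor B is the target density fold of the boosted class
  # inside inversions relative to the GENOME-WIDE average density (the
  # quantity the permutation enrichment test estimates). The implied
  # inside/outside density ratio is m = B(1-f)/(1-Bf), which exceeds B
  # because the boosted region itself inflates the genome-wide average.
  B <- cfg$repeat_boost_factor
  m <- if (B * f < 0.9) B * (1 - f) / (1 - B * f) else 10 * B * (1 - f)
  p_inside_boost <- m * f / (m * f + (1 - f))
  inside <- ifelse(boost, stats::runif(cfg$n_repeats) < p_inside_boost,
                   stats::runif(cfg$n_repeats) < f)
  place_in_region <- function(region, ls) {
    # pick a region interval able to hold each element, weighted by length
    ok_w <- function(L) pmax(0, (region$end - region$start) - L + 1)
    ctg <- character(length(ls)); st <- numeric(length(ls))
    for (L in unique(ls)) {
      sel <- which(ls == L)
      w <- ok_w(L)
      if (all(w == 0)) { # element longer than any interval: shrink to fit
        L2 <- max(region$end - region$start)
        ls[sel] <- L2
        w <- ok_w(L2)
        L <- L2
      }
      idx <- sample.int(nrow(region), length(sel), replace = TRUE, prob = w)
      st[sel] <- region$start[idx] +
        floor(stats::runif(length(sel)) * w[idx])
      ctg[sel] <- region$contig[idx]
    }
    data.frame(contig = ctg, start = st, end = st + ls,
               stringsAsFactors = FALSE)
  }
  rep_iv <- data.frame(contig = character(cfg$n_repeats),
                       start = numeric(cfg$n_repeats),
                       end = numeric(cfg$n_repeats), stringsAsFactors = FALSE)
  if (any(inside) && nrow(inv_u))
    rep_iv[inside, ] <- place_in_region(inv_u, lens[inside])
  if (any(!inside))
    rep_iv[!inside, ] <- place_in_region(out_u, lens[!inside])
  fam_index <- stats::setNames(seq_along(classes), names(classes))
  repeats <- data.frame(
    contig = rep_iv$contig, start = rep_iv$start, end = rep_iv$end,
    repeat_class = cls,
    family = sprintf("%s/%s-%d", cls, cls,
                     1 + (seq_len(cfg$n_repeats) %% 3)),
    divergence = round(stats::rbeta(cfg$n_repeats, 2, 3) * 50, 1),
    stringsAsFactors = FALSE)
  repeats <- repeats[order(repeats$contig, repeats$start, repeats$end), ]
  rownames(repeats) <- NULL

  # genes ---------------------------------------------------------------
  glens <- rlnorm_min(cfg$n_genes, cfg$gene_len_meanlog, cfg$gene_len_sdlog,
                      200)
  gi <- sample.int(nrow(cfg$genome), cfg$n_genes, replace = TRUE,
                   prob = cfg$genome$length)
  gst <- floor(stats::runif(cfg$n_genes) *
                 pmax(1, cfg$genome$length[gi] - glens))
  genes <- data.frame(contig = cfg$genome$contig[gi], start = gst,
                      end = gst + glens,
                      gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
                      mappable = stats::runif(cfg$n_genes) < cfg$prop_mappable,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$contig, genes$start, genes$end), ]
  rownames(genes) <- NULL

  # GO DAG: root -> 8 mid terms -> 40 leaf terms ------------------------
  mids <- sprintf("GO:M%02d", 1:8)
  leaves <- sprintf("GO:L%03d", 1:40)
  go_edges <- rbind(
    data.frame(child = mids, parent = "GO:ROOT", stringsAsFactors = FALSE),
    data.frame(child = leaves, parent = mids[1 + (seq_along(leaves) %% 8)],
               stringsAsFactors = FALSE))
  univ <- genes$gene_id[genes$mappable]
  n_ann <- pmin(3, 1 + stats::rpois(length(univ), 0.8))
  gene2term <- do.call(rbind, lapply(seq_along(univ), function(i)
    data.frame(gene = univ[i],
               term = sample(leaves, n_ann[i]), stringsAsFactors = FALSE)))
  # planted term: preferentially genes inside true inversions
  inside_ids <- genes_fully_inside(genes[genes$mappable, ],
                                   transform_inv_ids(inv_u))$gene_id
  n_pl <- min(15, length(univ))
  n_from_inv <- min(round(0.8 * n_pl), length(unique(inside_ids)))
  planted_genes <- c(sample(unique(inside_ids), n_from_inv),
                     sample(setdiff(univ, inside_ids),
                            max(0, n_pl - n_from_inv)))
  go_edges <- rbind(go_edges,
                    data.frame(child = "GO:PLANTED", parent = mids[1],
                               stringsAsFactors = FALSE))
  gene2term <- rbind(gene2term,
                     data.frame(gene = planted_genes, term = "GO:PLANTED",
                                stringsAsFactors = FALSE))

  # per-species alignments: blocks tile the complement of that species'
  # true deletions, mapped colinearly to a gapless query coordinate space
  species <- cfg$tree$tip.label
  alignments <- lapply(stats::setNames(species, species), function(sp) {
    dels <- truth[truth$sv_class == "DEL" &
                    vapply(strsplit(truth$species_present, ";", fixed = TRUE),
                           function(s) sp %in% s, TRUE),
                  c("contig", "start", "end")]
    comp <- iv_complement(dels, genome_iv)
    rows <- list()
    for (ctg in unique(comp$contig)) {
      x <- comp[comp$contig == ctg, ]
      widths <- x$end - x$start
      qs <- cumsum(c(0, widths[-length(widths)]))
      rows[[ctg]] <- data.frame(
        ref_contig = ctg, ref_start = x$start, ref_end = x$end,
        q_contig = paste0(sp, "_", ctg), q_start = qs, q_end = qs + widths,
        strand = "+", chain_id = paste0(sp, "_", ctg),
        stringsAsFactors = FALSE)
    }
    b <- do.call(rbind, rows)
    alignment_blocks(b$ref_contig, b$ref_start, b$ref_end, b$q_contig,
                     b$q_start, b$q_end, b$strand, b$chain_id)
  })

  list(repeats = repeats, genes = genes, go_edges = go_edges,
       gene2term = gene2term, alignments = alignments)
}

# minimal adapter: interval table -> consensus-like table for containment
transform_inv_ids <- function(iv) {
  data.frame(contig = iv$contig, start = iv$start, end = iv$end,
             consensus_id = sprintf("region_%04d", seq_len(nrow(iv))),
             stringsAsFactors = FALSE)
}
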