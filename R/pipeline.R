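#' Pipeline configuration
#'
#' Bundles all stage settings: the synthetic-data generator configuration,
#' per-caller filter thresholds, merge and size-band policies, enrichment
#' and GO settings, and the inversion size caps applied before gene
#' extraction (5 Mb for the lineage-subset analyses, 10 Mb for the
#' broader sweep).
#'
#' @param sim a [simulation_config()].
#' @param thresholds a [filter_thresholds()].
#' @param merge_pol a [merge_policy()].
#' @param band_pol a [size_band_policy()].
#' @param enrichment_n_samples permutation count for [enrichment_test()].
#' @param go_elim_cutoff,go_node_size settings for [go_enrichment_elim()].
#' @param inv_size_cap inversion length cap (nt) applied before gene
#'   containment analyses (default 5 Mb; the 10 Mb preset is
#'   `inv_size_cap = 1e7`).
#' @param del_floor_stage `"after_consensus"` (default) applies the 1 kb
#'   deletion floor after per-species consensus building and before
#'   cross-species merging; `"off"` disables it.
#' @param seed master seed; every stage derives its randomness from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            thresholds = filter_thresholds(),
                            merge_pol = merge_policy(),
                            band_pol = size_band_policy(),
                            enrichment_n_samples = 10000L,
                            go_elim_cutoff = 0.01, go_node_size = 5L,
                            inv_size_cap = 5e6,
                            del_floor_stage = c("after_consensus", "off"),
                            seed = 1L) {
  cfg <- list(sim = sim, thresholds = thresholds, merge_pol = merge_pol,
              band_pol = band_pol,
              enrichment_n_samples = as.integer(enrichment_n_samples),
              go_elim_cutoff = go_elim_cutoff,
              go_node_size = as.integer(go_node_size),
              inv_size_cap = inv_size_cap,
              del_floor_stage = match.arg(del_floor_stage),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Per-species consensus stage: filter, within-tool merge, two-tool
#' consensus
#'
#' @param calls_by_caller named list mapping caller to raw [sv_records()]
#'   of one species.
#' @param thresholds a [filter_thresholds()].
#' @param merge_pol a [merge_policy()].
#' @return named list mapping SV class to the species' consensus
#'   [sv_records()].
#' @export
species_consensus <- function(calls_by_caller,
                              thresholds = filter_thresholds(),
                              merge_pol = merge_policy()) {
  filtered <- lapply(calls_by_caller, filter_caller, t = thresholds)
  classes <- sort(unique(unlist(lapply(filtered, function(x) x$sv_class))))
  out <- list()
  for (cls in classes) {
    by_caller <- lapply(filtered, function(x)
      x[x$sv_class == cls, , drop = FALSE])
    by_caller <- lapply(by_caller, function(x)
      if (nrow(x)) merge_within_tool(x, merge_pol) else x)
    out[[cls]] <- build_consensus_set(by_caller, merge_pol)
  }
  out
}

#' Cross-species stage: size-conditional merge of all species' consensus
#' sets
#'
#' @param consensus_by_species named list (species) of named lists (class)
#'   of consensus [sv_records()], as produced by [species_consensus()].
#' @param band_pol a [size_band_policy()].
#' @param merge_pol a [merge_policy()].
#' @return a single [consensus_svs()] table over all classes.
#' @export
cross_species_stage <- function(consensus_by_species,
                                band_pol = size_band_policy(),
                                merge_pol = merge_policy()) {
  classes <- sort(unique(unlist(lapply(consensus_by_species, names))))
  pieces <- list()
  for (cls in classes) {
    per_species <- lapply(consensus_by_species, function(x)
      if (!is.null(x[[cls]])) x[[cls]] else empty_sv_records())
    merged <- conditional_merge_across_species(per_species, band_pol,
                                               merge_pol)
    pieces[[cls]] <- merged
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- consensus_svs(character(), numeric(), numeric(), character(),
                         character(), character(), character(), character())
  rownames(out) <- NULL
  class(out) <- c("consensus_svs", "data.frame")
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (col in names(df)[num]) df[[col]] <- fmt_num(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# stable 31-bit polynomial hash of a string, for config provenance
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates truth and caller call sets, writes and re-reads every file
#' format, filters, builds per-species and cross-species consensus sets,
#' reconstructs gains/losses under Dollo parsimony, and runs the
#' enrichment, GO, repeat-landscape, concordance and liftover analyses.
#' All outputs are plain TSV/BED/VCF files under `out_dir`; a manifest
#' records the seed and a configuration hash. Identical seeds yield
#' byte-identical output trees.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_sv_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls_dir <- file.path(out_dir, "calls")
  dir.create(calls_dir, showWarnings = FALSE)
  cfg <- config$sim
  cfg$seed <- config$seed
  tree <- cfg$tree
  species <- sort(tree$tip.label)

  # stage 1: truth ------------------------------------------------------
  truth <- simulate_sv_evolution(cfg)
  write_tsv(truth, file.path(out_dir, "truth_events.tsv"))

  # stage 2: caller call sets, written to disk and read back -------------
  consensus_by_species <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    calls <- simulate_caller_calls(truth, sp, cfg,
                                   seed = config$seed + 1000L * si)
    bd_path <- file.path(calls_dir, paste0(sp, "_breakdancer.tsv"))
    write_breakdancer_tsv(calls$breakdancer, bd_path)
    calls$breakdancer <- read_breakdancer_tsv(bd_path, sp)
    for (caller in setdiff(names(calls), "breakdancer")) {
      p <- file.path(calls_dir, paste0(sp, "_", caller, ".vcf"))
      write_sv_vcf(calls[[caller]], p)
      calls[[caller]] <- read_sv_vcf(p, sp, caller)
    }
    cons <- species_consensus(calls, config$thresholds, config$merge_pol)
    if (config$del_floor_stage == "after_consensus" && !is.null(cons$DEL))
      cons$DEL <- filter_deletion_size(cons$DEL, config$thresholds)
    consensus_by_species[[sp]] <- cons
  }

  # stage 3: cross-species merge ----------------------------------------
  svs <- cross_species_stage(consensus_by_species, config$band_pol,
                             config$merge_pol)
  write_sv_bed(svs, file.path(out_dir, "consensus.bed"))
  pres <- do.call(rbind, lapply(seq_len(nrow(svs)), function(i) {
    sp <- strsplit(svs$species_present[i], ";", fixed = TRUE)[[1]]
    stats::setNames(as.integer(species %in% sp), species)
  }))
  if (is.null(pres))
    pres <- matrix(integer(0), nrow = 0, ncol = length(species),
                   dimnames = list(NULL, species))
  presence <- cbind(data.frame(consensus_id = svs$consensus_id,
                               stringsAsFactors = FALSE),
                    as.data.frame(pres))
  write_tsv(presence, file.path(out_dir, "presence_matrix.tsv"))
  write_tsv(conservation_table(svs, species),
            file.path(out_dir, "conservation_table.tsv"))

  # stage 4: Dollo gains/losses -----------------------------------------
  recon <- reconstruct_events(svs, tree)
  write_tsv(recon, file.path(out_dir, "reconstruction.tsv"))
  branch_tables <- lapply(sort(unique(svs$sv_class)), function(cls)
    cbind(sv_class = cls,
          per_branch_summary(svs[svs$sv_class == cls, ], tree)))
  branch_summary <- do.call(rbind, branch_tables)
  if (is.null(branch_summary))
    branch_summary <- cbind(sv_class = character(0),
                            per_branch_summary(character(0), tree)[0, ])
  write_tsv(branch_summary, file.path(out_dir, "branch_summary.tsv"))

  # stage 5: size-vs-conservation rank tests -----------------------------
  write_tsv(size_by_conservation_tests(svs, species),
            file.path(out_dir, "size_tests.tsv"))

  # stage 6: annotation-dependent analyses ------------------------------
  ann <- simulate_annotation(cfg, truth, seed = config$seed + 90001L)
  write_repeatmasker_out(ann$repeats, file.path(out_dir, "repeats.out"))
  repeats <- parse_repeatmasker_out(file.path(out_dir, "repeats.out"))
  ws <- workspace(genomic_intervals(cfg$genome$contig, 0, cfg$genome$length))

  inv <- svs[svs$sv_class == "INV" &
               (svs$end - svs$start) <= config$inv_size_cap, , drop = FALSE]
  enr_rows <- list()
  for (rcls in intersect(c(cfg$repeat_boost_class, "DNA", "LTR"),
                         unique(repeats$repeat_class))) {
    track <- repeats[repeats$repeat_class == rcls, c("contig", "start", "end")]
    er <- enrichment_test(inv[, c("contig", "start", "end")], track, ws,
                          n_samples = config$enrichment_n_samples,
                          seed = config$seed + 70001L)
    enr_rows[[rcls]] <- data.frame(
      segments = "INV", track = rcls, observed = er$observed_overlap,
      expected = er$expected_overlap, fold = er$fold_change,
      p = er$p_empirical, direction = er$direction,
      stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, enr_rows), file.path(out_dir, "enrichment.tsv"))

  # GO enrichment on genes fully inside inversions, per lineage subset --
  dag <- go_dag(ann$go_edges, ann$gene2term)
  universe <- ann$genes$gene_id[ann$genes$mappable]
  subsets <- lineage_subsets(svs, tree)
  go_rows <- list()
  for (nm in names(subsets)) {
    sel <- inv[inv$consensus_id %in% subsets[[nm]], , drop = FALSE]
    study <- intersect(genes_fully_inside(ann$genes, sel)$gene_id, universe)
    if (length(study) < 2) next
    res <- go_enrichment_elim(study, universe, dag,
                              elim_cutoff = config$go_elim_cutoff,
                              node_size = config$go_node_size)
    if (nrow(res))
      go_rows[[nm]] <- cbind(subset = nm, n_genes = length(study), res)
  }
  if (length(go_rows))
    write_tsv(do.call(rbind, go_rows), file.path(out_dir, "go_enrichment.tsv"))
  else
    write_tsv(data.frame(subset = character(), n_genes = integer(),
                         term = character(), annotated = integer(),
                         significant = integer(), expected = numeric(),
                         p_elim = numeric()),
              file.path(out_dir, "go_enrichment.tsv"))

  # repeat landscape inside/outside inversions ---------------------------
  write_tsv(repeat_landscape(inv[, c("contig", "start", "end")], repeats, ws),
            file.path(out_dir, "repeat_landscape.tsv"))

  # deletion concordance for the focal (first) species -------------------
  focal <- species[1]
  for (sp in species) {
    write_alignment_bed(ann$alignments[[sp]],
                        file.path(out_dir, paste0("alignment_", sp, ".bed")))
  }
  blocks <- read_alignment_bed(file.path(out_dir,
                                         paste0("alignment_", focal, ".bed")))
  dels_focal <- svs[svs$sv_class == "DEL" &
                      vapply(strsplit(svs$species_present, ";", fixed = TRUE),
                             function(s) focal %in% s, TRUE), , drop = FALSE]
  conc <- deletion_concordance(dels_focal, blocks)
  write_tsv(conc$verdicts, file.path(out_dir, "concordance_verdicts.tsv"))
  write_tsv(data.frame(species = focal, n_deletions = nrow(dels_focal),
                       discordant = conc$discordant_count,
                       discordant_fraction = conc$discordant_fraction),
            file.path(out_dir, "concordance_summary.tsv"))

  # liftover of consensus SVs to every species ---------------------------
  lift_rows <- lapply(species, function(sp) {
    blocks_sp <- ann$alignments[[sp]]
    mapped <- vapply(seq_len(nrow(svs)), function(i)
      !is.null(liftover_interval(svs[i, c("contig", "start", "end")],
                                 blocks_sp)), TRUE)
    data.frame(species = sp, n_svs = nrow(svs), n_mapped = sum(mapped),
               n_unmapped = sum(!mapped), stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, lift_rows),
            file.path(out_dir, "liftover_summary.tsv"))

  # manifest -------------------------------------------------------------
  cfg_text <- yaml::as.yaml(list(
    seed = config$seed,
    enrichment_n_samples = config$enrichment_n_samples,
    inv_size_cap = config$inv_size_cap,
    del_floor_stage = config$del_floor_stage,
    tree = cfg$tree_newick,
    gain_rate = as.list(cfg$gain_rate),
    loss_rate = cfg$loss_rate))
  writeLines(c(sprintf("svlineage_version\t%s",
                       as.character(utils::packageVersion("svlineage"))),
               sprintf("seed\t%d", config$seed),
               sprintf("config_hash\t%s", config_hash(cfg_text))),
             file.path(out_dir, "manifest.tsv"))
  writeLines(cfg_text, file.path(out_dir, "config.yaml"))

  invisible(list(truth = truth, svs = svs, recon = recon,
                 branch_summary = branch_summary,
                 concordance = conc,
                 consensus_by_species = consensus_by_species))
}

#' Lineage subsets of consensus events used for the gene analyses
#'
#' Species-specific (per species), shared by at least two species, the
#' two-species sister pair, that pair plus its closest relative, and the
#' events present in all species — parameterized over the tree's leaf
#' names (for the default radiation tree: Mzebra+Pnyererei,
#' Mzebra+Pnyererei+Hburtoni, conserved).
#'
#' @param svs [consensus_svs()] table.
#' @param tree rooted `phylo` object.
#' @return named list mapping subset name to consensus ids.
#' @export
lineage_subsets <- function(svs, tree) {
  species <- sort(tree$tip.label)
  br <- tree_branches(tree)
  internal <- br$branch[!br$branch %in% species & !br$is_root]
  internal <- internal[order(nchar(internal))]
  sp_sets <- strsplit(svs$species_present, ";", fixed = TRUE)
  n_sp <- lengths(sp_sets)
  out <- list()
  for (sp in species)
    out[[paste0("specific_", sp)]] <-
      svs$consensus_id[n_sp == 1 & svs$species_present == sp]
  out[["shared_2plus"]] <- svs$consensus_id[n_sp > 1]
  for (b in internal) {
    clade <- sort(strsplit(b, "+", fixed = TRUE)[[1]])
    out[[paste0("clade_", b)]] <- svs$consensus_id[
      vapply(sp_sets, function(s) identical(sort(s), clade), TRUE)]
  }
  out[["conserved"]] <- svs$consensus_id[n_sp == length(species)]
  out
}
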