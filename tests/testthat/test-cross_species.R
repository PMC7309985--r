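band <- size_band_policy()

test_that("size bands are bottom-inclusive with the stated thresholds", {
  expect_equal(band_threshold(band, c(0, 499, 500, 999, 1000, 9999, 10000, 1e6)),
               c(0.50, 0.50, 0.80, 0.80, 0.90, 0.90, 0.95, 0.95))
  expect_error(size_band_policy(data.frame(lower = c(0, 600),
                                           upper = c(500, Inf),
                                           threshold = c(0.5, 0.9))),
               "partition")
})

test_that("cross-species merging applies the size-conditional thresholds", {
  mk <- function(sp, start, end)
    make_records(start, end, species = sp, caller = "delly")
  # two 400 nt calls overlapping 60% reciprocally -> merged (50% band)
  m <- conditional_merge_across_species(
    list(a = mk("a", 0, 400), b = mk("b", 160, 560)), band)
  expect_equal(nrow(m), 1)
  expect_equal(m$species_present, "a;b")

  # two 5 kb calls overlapping ~85% -> NOT merged (90% band)
  m2 <- conditional_merge_across_species(
    list(a = mk("a", 0, 5000), b = mk("b", 750, 5750)), band)
  expect_equal(nrow(m2), 2)

  # 900 nt vs 1200 nt overlapping ~85%: stricter band (90%) governs
  a <- mk("a", 300, 1200); b <- mk("b", 0, 1200)
  ro <- oracle_ro(rbind(a, b), 1, 2)
  expect_gte(ro, 0.75)
  expect_lt(ro, 0.90)
  m3 <- conditional_merge_across_species(list(a = a, b = b), band)
  expect_equal(nrow(m3), 2)
})

test_that("cross-species merge equals brute force and ignores input order", {
  for (seed in 1:3) {
    set.seed(seed)
    per_sp <- list(
      sp1 = random_interval_records(60, span = 5e4, len_range = c(100, 20000),
                                    species = "sp1"),
      sp2 = random_interval_records(60, span = 5e4, len_range = c(100, 20000),
                                    species = "sp2"),
      sp3 = random_interval_records(50, span = 5e4, len_range = c(100, 20000),
                                    species = "sp3"))
    merged <- conditional_merge_across_species(per_sp, band)
    pooled <- sort_sv_records(do.call(rbind, unname(per_sp)))
    comp <- oracle_components(pooled, function(i, j) {
      thr <- max(band_threshold(band, pooled$end[i] - pooled$start[i]),
                 band_threshold(band, pooled$end[j] - pooled$start[j]))
      oracle_ro(pooled, i, j) >= thr
    })
    expect_equal(nrow(merged), length(unique(comp)))

    shuffled <- conditional_merge_across_species(rev(per_sp), band)
    expect_equal(as.data.frame(merged), as.data.frame(shuffled))
  }
})

test_that("conservation classes and Table-1-style counts are consistent", {
  all_sp <- c("Hburtoni", "Mzebra", "Nbrichardi", "Pnyererei")
  svs <- consensus_svs(
    contig = "lg1", start = c(0, 5000, 10000), end = c(1000, 6000, 11000),
    sv_class = "DEL",
    species_present = c("Mzebra", "Mzebra;Pnyererei",
                        "Hburtoni;Mzebra;Nbrichardi;Pnyererei"),
    callers_by_species = c("Mzebra=delly|pindel",
                           "Mzebra=delly|pindel;Pnyererei=delly|pindel",
                           paste(paste0(all_sp, "=delly|pindel"),
                                 collapse = ";")),
    source_records = "r", consensus_id = c("d1", "d2", "d3"))
  cc <- classify_conservation(svs, all_sp)
  expect_equal(cc$n_species, c(1L, 2L, 4L))
  expect_equal(cc$conserved, c(FALSE, FALSE, TRUE))
  tab <- conservation_table(svs, all_sp)
  expect_equal(tab$total, 3L)
  expect_equal(tab$multi_species, 2L)
  expect_equal(tab$all_species, 1L)
  expect_error(classify_conservation(svs, c("Mzebra", "Pnyererei")),
               "not in the analyzed set")
})

test_that("counts always satisfy Total >= multi-species >= all-species", {
  set.seed(31)
  sim <- simulation_config(seed = 31)
  truth <- simulate_sv_evolution(sim)
  svs <- consensus_svs(truth$contig, truth$start,
                       pmax(truth$end, truth$start + 1), truth$sv_class,
                       truth$species_present,
                       vapply(strsplit(truth$species_present, ";", fixed = TRUE),
                              function(s) paste(paste0(s, "=delly|pindel"),
                                                collapse = ";"), ""),
                       truth$event_id, truth$event_id)
  tab <- conservation_table(svs, sort(sim$tree$tip.label))
  expect_true(all(tab$total >= tab$multi_species))
  expect_true(all(tab$multi_species >= tab$all_species))
})

test_that("Mann-Whitney size tests match the exact permutation example", {
  svs <- consensus_svs(
    contig = "lg1", start = c(0, 10, 20, 30, 40, 50) * 1000,
    end = c(0, 10, 20, 30, 40, 50) * 1000 + c(1, 2, 3, 4, 5, 6),
    sv_class = "DUP",
    species_present = c(rep("Mzebra", 3),
                        rep("Mzebra;Pnyererei", 3)),
    callers_by_species = c(rep("Mzebra=delly|pindel", 3),
                           rep("Mzebra=delly|pindel;Pnyererei=delly|pindel", 3)),
    source_records = "r", consensus_id = sprintf("e%d", 1:6))
  res <- size_by_conservation_tests(svs, c("Mzebra", "Pnyererei"))
  expect_equal(res$U, 0)
  # exhaustive permutation oracle over C(6,3) = 20 arrangements
  sizes <- c(1, 2, 3, 4, 5, 6)
  stats <- apply(utils::combn(6, 3), 2, function(ix) {
    sum(outer(sizes[ix], sizes[-ix], ">")) +
      0.5 * sum(outer(sizes[ix], sizes[-ix], "=="))
  })
  p_exact <- mean(abs(stats - 4.5) >= abs(0 - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p, 0.1)
  expect_equal(res$direction, "1 < 2")

  # identical samples -> p = 1, no direction
  svs$end <- svs$start + rep(c(5, 5, 5), 2)
  res2 <- size_by_conservation_tests(svs, c("Mzebra", "Pnyererei"))
  expect_equal(res2$p, 1)
  expect_equal(res2$direction, "")
})

test_that("shifted log-normal sizes give a significant, correct direction", {
  set.seed(8)
  n <- 200
  mk_cons <- function(sizes, sp, cbs, off) {
    start <- seq_along(sizes) * 1e5 + off
    consensus_svs("lg9", start, start + sizes, "INV",
                  sp, cbs, "r", sprintf("i%d_%d", off, seq_along(sizes)))
  }
  small <- round(rlnorm(n, 7, 0.5))
  big <- round(rlnorm(n, 7.6, 0.5))
  svs <- rbind(mk_cons(small, "Mzebra", "Mzebra=delly|pindel", 1),
               mk_cons(big, "Mzebra;Pnyererei",
                       "Mzebra=delly|pindel;Pnyererei=delly|pindel", 2))
  class(svs) <- c("consensus_svs", "data.frame")
  res <- size_by_conservation_tests(svs, c("Mzebra", "Pnyererei"))
  expect_lt(res$p, 0.001)
  expect_equal(res$direction, "1 < 2")
})
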