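test_that("RepeatMasker class/field mapping and round trip", {
  rm <- data.frame(contig = c("lg1", "lg1", "lg2"),
                   start = c(10, 500, 40), end = c(110, 720, 300),
                   repeat_class = c("SINE", "DNA", "Other"),
                   family = c("SINE/SINE2", "DNA/TcMar", "Weird/Thing"),
                   divergence = c(12.3, 4.0, 33.1),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(rm, path)
  back <- parse_repeatmasker_out(path)
  expect_equal(back$repeat_class, c("SINE", "DNA", "Other"))
  expect_equal(back$divergence, c(12.3, 4.0, 33.1))
  expect_equal(back$start, rm$start)
  expect_equal(back$end, rm$end)
  expect_equal(back$family, rm$family)
})

test_that("malformed RepeatMasker rows are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "",
               "  250  12.3  0.0  0.0  lg1  11  110  (0) + SINE2  SINE/SINE2  1  100  (0)  1",
               "  250  not_numeric  0.0  0.0  lg1  5  50  (0) + X  DNA/h  1  45  (0)  2"),
             path)
  expect_warning(out <- parse_repeatmasker_out(path), "malformed")
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 10)
})

test_that("repeat landscape proportions follow the containment rule", {
  ws <- workspace(genomic_intervals("c", 0, 1000))
  sv <- genomic_intervals("c", 0, 100)
  reps <- data.frame(contig = "c", start = c(10, 90, 400),
                     end = c(60, 110, 500),
                     repeat_class = c("LTR", "LTR", "DNA"),
                     family = "x", divergence = c(7, 7, 12),
                     stringsAsFactors = FALSE)
  land <- repeat_landscape(sv, reps, ws, bin_width = 5)
  inside_ltr <- land[land$region == "inside" & land$repeat_class == "LTR" &
                       land$bin_low == 5, ]
  expect_equal(inside_ltr$proportion, 0.5)  # 50 nt of the 100 nt SV space
  # straddling element [90,110) counted in neither region
  outside_ltr <- land[land$region == "outside" & land$repeat_class == "LTR", ]
  expect_equal(sum(outside_ltr$nt), 0)
  outside_dna <- land[land$region == "outside" & land$repeat_class == "DNA" &
                        land$bin_low == 10, ]
  expect_equal(outside_dna$proportion, 100 / 900)
  # no repeats -> all zero
  land0 <- repeat_landscape(sv, reps[0, ], ws)
  expect_true(all(land0$proportion == 0))
})

test_that("inside plus outside equals the genome space", {
  set.seed(4)
  ws <- workspace(genomic_intervals(c("a", "b"), 0, c(5e4, 3e4)))
  s <- sort(sample.int(4e4, 10)) * 1
  sv <- data.frame(contig = "a", start = s, end = s + 800)
  inside <- svlineage:::iv_total_nt(iv_intersect(sv, ws$intervals))
  outside <- svlineage:::iv_total_nt(iv_complement(sv, ws$intervals))
  expect_equal(inside + outside, 8e4)
})

test_that("deletion concordance follows the 50%-span rule", {
  dels <- data.frame(contig = "c", start = 100, end = 200,
                     consensus_id = "d1", stringsAsFactors = FALSE)
  blk <- function(s, e) alignment_blocks("c", s, e, "q", 1000 + s, 1000 + e,
                                         "+", "ch1")
  expect_true(deletion_concordance(dels, blk(140, 400))$verdicts$discordant)
  expect_false(deletion_concordance(dels, blk(180, 400))$verdicts$discordant)
  far <- alignment_blocks("c", 5000, 6000, "q", 0, 1000, "+", "ch2")
  res <- deletion_concordance(dels, far)
  expect_false(res$verdicts$discordant)
  expect_equal(res$discordant_fraction, 0)
  expect_error(deletion_concordance(
    data.frame(contig = "c", start = 5, end = 5, consensus_id = "z"),
    blk(0, 10)), "zero-length")
})

test_that("concordance verdicts equal a brute-force block scan", {
  set.seed(23)
  s <- sort(sample.int(9e4, 30))
  dels <- data.frame(contig = "c", start = s, end = s + 1000,
                     consensus_id = sprintf("d%02d", 1:30),
                     stringsAsFactors = FALSE)
  bs <- sort(sample.int(9e4, 40))
  blocks <- alignment_blocks("c", bs, bs + 1500, "q",
                             seq_along(bs) * 3000, seq_along(bs) * 3000 + 1500,
                             "+", sprintf("ch%02d", 1:40))
  res <- deletion_concordance(dels, blocks)
  for (i in 1:30) {
    ov <- pmax(0, pmin(blocks$ref_end, dels$end[i]) -
                 pmax(blocks$ref_start, dels$start[i]))
    expect_equal(res$verdicts$discordant[i], max(ov) / 1000 >= 0.5)
  }
})

test_that("liftover matches offset arithmetic on both strands", {
  plus <- alignment_blocks("r", 0, 100, "q", 500, 600, "+", "c1")
  got <- liftover_interval(list(contig = "r", start = 10, end = 20), plus)
  expect_equal(got$start, 510)
  expect_equal(got$end, 520)

  minus <- alignment_blocks("r", 0, 100, "q", 500, 600, "-", "c1")
  got2 <- liftover_interval(list(contig = "r", start = 0, end = 10), minus)
  expect_equal(got2$start, 590)
  expect_equal(got2$end, 600)

  # endpoint outside all blocks -> unmapped
  expect_null(liftover_interval(list(contig = "r", start = 50, end = 150),
                                plus))
  expect_error(alignment_blocks("r", c(0, 50), c(60, 100), "q", c(0, 50),
                                c(60, 100), "+", "bad"),
               "overlapping reference")
})

test_that("minus-strand mapping equals a per-base map oracle", {
  minus <- alignment_blocks("r", c(0, 200), c(100, 300), "q",
                            c(700, 500), c(800, 600), "-", "c1")
  # per-base map: ref position p in block -> q_end - 1 - (p - ref_start)
  base_map <- function(p) {
    b <- minus[minus$ref_start <= p & p < minus$ref_end, ]
    b$q_end - 1 - (p - b$ref_start)
  }
  set.seed(31)
  for (i in 1:20) {
    s <- sample(c(0:95, 200:295), 1)
    len <- sample.int(5, 1)
    last <- s + len - 1
    if (!(last < 100 || (last >= 200 & last < 300))) next
    got <- liftover_interval(list(contig = "r", start = s, end = s + len),
                             minus)
    expect_equal(got$start, min(base_map(s), base_map(last)))
    expect_equal(got$end, max(base_map(s), base_map(last)) + 1)
  }
  # interval spanning both blocks of the chain
  got <- liftover_interval(list(contig = "r", start = 90, end = 210), minus)
  expect_equal(got$start, base_map(209))
  expect_equal(got$end, base_map(90) + 1)
})

test_that("liftover round trip through the inverted chain is the identity", {
  set.seed(91)
  blocks <- alignment_blocks(
    "r", c(0, 150, 400), c(100, 300, 450), "q",
    c(900, 650, 500), c(1000, 800, 550), "-", "ch")
  for (i in 1:25) {
    s <- sample.int(440, 1); len <- sample.int(40, 1)
    fwd <- liftover_interval(list(contig = "r", start = s, end = s + len),
                             blocks)
    if (is.null(fwd)) next
    back <- liftover_interval(fwd[, c("contig", "start", "end")],
                              invert_chain(blocks))
    expect_equal(back$start, s)
    expect_equal(back$end, s + len)
  }
  plus_blocks <- alignment_blocks("r", c(0, 150), c(100, 300), "q",
                                  c(20, 170), c(120, 320), "+", "p")
  fwd <- liftover_interval(list(contig = "r", start = 40, end = 260),
                           plus_blocks)
  back <- liftover_interval(fwd[, c("contig", "start", "end")],
                            invert_chain(plus_blocks))
  expect_equal(back$start, 40)
  expect_equal(back$end, 260)
})

test_that("alignment BED write/read round trips", {
  blocks <- alignment_blocks(c("r1", "r1"), c(0, 300), c(100, 400),
                             "qq", c(50, 350), c(150, 450), "+", "chain7")
  path <- withr::local_tempfile(fileext = ".bed")
  write_alignment_bed(blocks, path)
  back <- read_alignment_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(blocks))
})
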