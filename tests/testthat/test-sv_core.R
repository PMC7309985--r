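test_that("VCF coordinates and flags are normalized on read", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "lg1\t101\td1\tN\t<DEL>\t300\tPASS\tSVTYPE=DEL;END=200;LIBS=3;PE=9;PRECISE",
    "lg1\t500\td2\tN\t<DUP>\t120\tLowQual\tSVTYPE=DUP;END=900;IMPRECISE"),
    path)
  rec <- read_sv_vcf(path, "Mzebra", "delly")
  expect_equal(rec$start, c(100, 499))
  expect_equal(rec$end, c(200, 900))
  expect_equal(rec$sv_class, c("DEL", "DUP"))
  expect_equal(rec$filter_pass, c(TRUE, FALSE))
  expect_equal(rec$precise, c(TRUE, FALSE))
  expect_equal(rec$n_libraries, c(3L, 0L))
  expect_equal(rec$n_read_pairs, c(9L, 0L))
})

test_that("unknown SVTYPE is skipped with a warning, malformed lines error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "lg1\t101\tx1\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=200",
    "lg1\t301\tx2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=400"), path)
  expect_warning(rec <- read_sv_vcf(path, "sp", "delly"), "SVTYPE")
  expect_equal(rec$record_id, "x2")

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "lg1\t101\tonly4cols\tN"), bad)
  expect_error(read_sv_vcf(bad, "sp", "delly"), "line 3")
})

test_that("VCF write-then-read round trip is the identity", {
  rec <- sv_records(
    contig = c("lg1", "lg1", "lg2"), start = c(100, 900, 50),
    end = c(600, 2000, 51), sv_class = c("DEL", "INV", "INS"),
    species = "Pnyererei", caller = "pindel",
    n_libraries = c(2L, 4L, 3L), n_read_pairs = c(7L, 12L, 6L),
    score = c(NA, NA, NA), filter_pass = c(TRUE, TRUE, FALSE),
    precise = c(TRUE, FALSE, TRUE), insertion_length = c(0L, 0L, 240L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(rec, path)
  back <- read_sv_vcf(path, "Pnyererei", "pindel")
  expect_equal(as.data.frame(back), as.data.frame(sort_sv_records(rec)))
})

test_that("Breakdancer rows map fields, types and libraries correctly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "lg1\t1001\tlg1\t3000\tDEL\t2000\t99\t7\tlibA:4|libB:3",
    "lg2\t500\tlg5\t9000\tCTX\t0\t87\t5\tlibA:5"), path)
  rec <- read_breakdancer_tsv(path, "Mzebra")
  del <- rec[rec$sv_class == "DEL", ]
  expect_equal(del$start, 1000)
  expect_equal(del$end, 3000)
  expect_equal(del$score, 99)
  expect_equal(del$n_read_pairs, 7L)
  expect_equal(del$n_libraries, 2L)
  tra <- rec[rec$sv_class == "TRA", ]
  expect_equal(tra$mate_contig, "lg5")
  expect_equal(tra$mate_end, 9000)
  expect_equal(tra$n_libraries, 1L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("lg1\t10\tlg1\t20\tDEL\t10\tnot_a_number\t4\tlibA:4", bad)
  expect_error(read_breakdancer_tsv(bad, "sp"), "non-numeric")
})

test_that("Breakdancer write-then-read round trips interval content", {
  set.seed(11)
  rec <- random_interval_records(5, caller = "breakdancer")
  rec$score <- 99
  path <- withr::local_tempfile(fileext = ".tsv")
  write_breakdancer_tsv(rec, path)
  back <- read_breakdancer_tsv(path, "sp1")
  expect_equal(nrow(back), 5)
  ord <- sort_sv_records(rec)
  expect_equal(back$start, ord$start)
  expect_equal(back$end, ord$end)
  expect_equal(back$n_read_pairs, ord$n_read_pairs)
  expect_true(!is.unsorted(back$start[back$contig == "lg1"]))
})

test_that("reciprocal overlap matches direct arithmetic and is symmetric", {
  a <- genomic_intervals("c", 100, 200)
  b <- genomic_intervals("c", 150, 250)
  expect_equal(reciprocal_overlap(a, b), 0.5)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(genomic_intervals("c", 0, 100),
                                  genomic_intervals("c", 100, 200)), 0)
  expect_equal(reciprocal_overlap(a, genomic_intervals("d", 100, 200)), 0)
  expect_error(reciprocal_overlap(list(contig = "c", start = 5, end = 5), a),
               "zero-length")
  set.seed(42)
  for (i in 1:50) {
    s <- sort(sample.int(1000, 4, replace = TRUE))
    x <- list(contig = "c", start = s[1], end = s[2] + 1)
    y <- list(contig = "c", start = s[3], end = s[4] + 1)
    expect_equal(reciprocal_overlap(x, y), reciprocal_overlap(y, x))
  }
})

test_that("BED6 output is bit-exact and round trips", {
  svs <- consensus_svs("chr1", 100, 200, "DEL", "Mzebra;Pnyererei",
                       "Mzebra=delly;Pnyererei=delly", "r1|r2", "id", 10)
  path <- withr::local_tempfile(fileext = ".bed")
  write_sv_bed(svs, path)
  expect_identical(readLines(path), "chr1\t100\t200\tid\t2\tDEL")

  write_sv_bed(svs[0, ], path)
  expect_identical(readLines(path), character(0))

  set.seed(3)
  n <- 10
  start <- sort(sample.int(1e5, n))
  svs10 <- consensus_svs("lg2", start, start + 500, "INV", "Hburtoni",
                         "Hburtoni=pindel", sprintf("r%d", 1:n),
                         sprintf("inv_%03d", 1:n))
  write_sv_bed(svs10, path)
  back <- read_sv_bed(path)
  expect_equal(back$start, svs10$start)
  expect_equal(back$consensus_id, svs10$consensus_id)
  expect_equal(back$n_species, rep(1L, n))
})

test_that("1-based/0-based conversion round trips", {
  s1 <- c(1, 101, 5000); e1 <- c(10, 200, 5000)
  internal <- svlineage:::from_1based(s1, e1)
  back <- svlineage:::to_1based(internal$start, internal$end)
  expect_equal(back$start1, s1)
  expect_equal(back$end1, e1)
  expect_equal(internal$end - internal$start, e1 - s1 + 1)
})

test_that("interval set algebra matches per-nucleotide brute force", {
  set.seed(9)
  for (rep_i in 1:5) {
    mk <- function(n) {
      s <- sample.int(1900, n)
      data.frame(contig = sample(c("a", "b"), n, replace = TRUE),
                 start = s, end = s + sample.int(120, n))
    }
    a <- mk(8); b <- mk(8)
    expect_equal(overlap_nucleotides(a, b), oracle_overlap_nt(a, b))
    genome <- data.frame(contig = c("a", "b"), start = 0, end = 2100)
    comp <- iv_complement(a, genome)
    expect_equal(svlineage:::iv_total_nt(comp) + svlineage:::iv_total_nt(a),
                 4200)
    expect_equal(overlap_nucleotides(a, comp), 0)
  }
})
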