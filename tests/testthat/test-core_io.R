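test_that("BED reading maps fields verbatim and round-trips byte-identically", {
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), f3)
  bed <- read_bed(f3)
  expect_equal(bed$chrom, c("chr1", "chr2"))
  expect_equal(bed$start, c(100, 0))
  expect_equal(bed$end, c(200, 50))
  expect_false("strand" %in% names(bed))

  f6 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t0\t50\tpeakA\t0\t-", "chr1\t7\t9\tpeakB\t3\t+"), f6)
  bed6 <- read_bed(f6)
  expect_equal(bed6$name, c("peakA", "peakB"))
  expect_equal(bed6$strand, c("-", "+"))

  for (f in c(f3, f6)) {
    out <- withr::local_tempfile(fileext = ".bed")
    write_bed(read_bed(f), out)
    expect_identical(readBin(out, "raw", file.size(out)),
                     readBin(f, "raw", file.size(f)))
  }
})

test_that("malformed BED lines raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t0\t10", "chr1\tzero\t100"), f)
  expect_error(read_bed(f), "line 2")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "no such file")
})

test_that("interval invariants are enforced", {
  expect_error(genomic_intervals("chr1", 200, 100), "start >= end")
  expect_error(genomic_intervals("", 0, 10), "chromosome")
  expect_error(genomic_intervals("chr1", -5, 10), "negative")
  expect_silent(validate_intervals(genomic_intervals("chr1", 0, 1)))
})

test_that("fragment counting assigns by midpoint under the half-open rule", {
  frag <- genomic_intervals("chr1", c(100, 300), c(150, 350))
  expect_equal(count_fragments_in(frag, genomic_intervals("chr1", 0, 200)), 1L)
  expect_equal(count_fragments_in(genomic_intervals(character(), numeric(), numeric()),
                                  genomic_intervals("chr1", 0, 200)), 0L)
  # midpoint exactly at the region end is excluded
  edge <- genomic_intervals("chr1", 190, 210)
  expect_equal(count_fragments_in(edge, genomic_intervals("chr1", 0, 200)), 0L)
  expect_equal(count_fragments_in(edge, genomic_intervals("chr1", 200, 400)), 1L)
})

test_that("midpoint counting conserves the library over a partition", {
  withr::with_seed(5, {
    start <- sort(sample(0:9800, 500, replace = TRUE))
    frag <- genomic_intervals("chr1", start, start + sample(50:200, 500, TRUE))
  })
  bins <- genomic_intervals("chr1", seq(0, 9000, by = 1000), seq(1000, 10000, by = 1000))
  expect_equal(sum(count_fragments_in(frag, bins)), 500L)
})

test_that("CPM normalization is exact and linear", {
  expect_equal(cpm_normalize(500, 1e6), 500)
  expect_equal(cpm_normalize(0, 123), 0)
  expect_equal(cpm_normalize(3, 2e6), 1.5)
  expect_error(cpm_normalize(1, 0), "library_size")
  a <- 17; b <- 41
  expect_equal(cpm_normalize(a + b, 5e5),
               cpm_normalize(a, 5e5) + cpm_normalize(b, 5e5))
})

test_that("binned tracks place midpoints, normalize, and conserve fragments", {
  sizes <- c(chr1 = 5000)
  one <- fragment_set(genomic_intervals("chr1", 1400, 1600))
  tr <- make_binned_track(one, sizes, 1000)
  expect_equal(tr$values$chr1, c(0, 1e6, 0, 0, 0))
  empty <- fragment_set(genomic_intervals(character(), numeric(), numeric()))
  expect_true(all(unlist(make_binned_track(empty, sizes, 1000)$values) == 0))
  two <- fragment_set(genomic_intervals(c("chr1", "chr1"), c(1100, 1700), c(1300, 1900)))
  expect_equal(make_binned_track(two, sizes, 1000)$values$chr1[2], 1e6)
  expect_error(make_binned_track(one, c(chrX = 1000), 1000), "absent")
  raw <- make_binned_track(two, sizes, 1000, normalize = FALSE)
  expect_equal(sum(unlist(raw$values)), 2)
})

test_that("track correlation behaves at the extremes and under independence", {
  # two independent tracks with ~Poisson(5) counts in 10,000 bins
  sizes <- c(chr1 = 1e6)
  withr::with_seed(11, {
    mk <- function() {
      mids <- sample(0:999999, 50000, replace = TRUE)
      fragment_set(genomic_intervals("chr1", pmax(0, mids - 5), pmax(0, mids - 5) + 10))
    }
    a <- make_binned_track(mk(), sizes, 100)
    b <- make_binned_track(mk(), sizes, 100)
  })
  expect_equal(track_pearson(a, a), 1)
  flipped <- a
  flipped$values$chr1 <- max(a$values$chr1) - a$values$chr1
  expect_equal(track_pearson(a, flipped), -1)
  expect_lt(abs(track_pearson(a, b)), 0.05)
  const <- a
  const$values$chr1 <- rep(1, length(a$values$chr1))
  expect_error(track_pearson(a, const), "zero variance")
  wide <- make_binned_track(fragment_set(genomic_intervals("chr1", 0, 10)), sizes, 200)
  expect_error(track_pearson(a, wide), "bin widths")
})

test_that("edge-to-edge interval gaps follow the counting rule", {
  g <- function(s1, e1, s2, e2, c1 = "chr1", c2 = "chr1")
    interval_gap(genomic_intervals(c1, s1, e1), genomic_intervals(c2, s2, e2))
  expect_equal(g(100, 200, 150, 250), 0)
  expect_equal(g(100, 200, 260, 300), 60)
  expect_equal(g(100, 200, 301, 400), 101)
  expect_equal(g(100, 200, 200, 300), 0)  # touching
  expect_equal(g(260, 300, 100, 200), 60) # symmetric
  expect_equal(g(0, 10, 0, 10, "chr1", "chr2"), Inf)
})

test_that("chrom-sizes and TSS tables round-trip", {
  f <- withr::local_tempfile()
  write_chrom_sizes(c(chr1 = 1e6, chr2 = 25000), f)
  expect_equal(read_chrom_sizes(f), c(chr1 = 1e6, chr2 = 25000))
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(100, 900))
  f2 <- withr::local_tempfile()
  write_tss_table(tss, f2)
  expect_equal(read_tss_table(f2), tss)
  expect_error(validate_tss(data.frame(gene_id = c("a", "a"), chrom = "c",
                                       strand = "+", tss = 1)), "duplicate")
})
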