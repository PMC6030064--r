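test_that("upper-tail Poisson p-values match pmf summation", {
  # frozen values computed with the independent pmf-summation oracle
  expect_equal(poisson_upper_pvalue(10, 2), 4.6498075017e-05, tolerance = 1e-9)
  expect_equal(poisson_upper_pvalue(5, 5), 0.55950671493, tolerance = 1e-10)
  expect_equal(poisson_upper_pvalue(0, 0.01), 1)
  expect_equal(poisson_upper_pvalue(0, 1e6), 1)
  for (lam in c(0.5, 1, 2, 5, 10, 20))
    for (k in 0:50)
      expect_lt(abs(poisson_upper_pvalue(k, lam) - oracle_pois_tail(k, lam)), 1e-10)
  expect_error(poisson_upper_pvalue(3, 0), "lam")
  expect_error(poisson_upper_pvalue(-1, 2), "non-negative")
  expect_error(poisson_upper_pvalue(2.5, 2), "integer")
})

test_that("BH adjustment reproduces the explicit step-up and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
      perm <- sample(seq_along(p))
      expect_equal(bh_adjust(p[perm]), q[perm])       # permutation invariance
      expect_true(all(q >= p - 1e-15))                # step-up can only raise
    }
  })
})

test_that("the window test is symmetric and gates on normalized fold", {
  # enrichment: 100 observed vs an input-implied rate near 20
  tw <- test_window(100, 20, 1e6, 1e6)
  expect_lt(tw$p_enrich, 1e-15)
  expect_equal(tw$p_enrich, poisson_upper_pvalue(100, 20.5))
  expect_gt(tw$log2_ratio, 1)
  # equal normalized signal: ratio exactly 0
  eq <- test_window(50, 50, 1e6, 1e6)
  expect_equal(eq$log2_ratio, 0)
  # swapping chip and input swaps directions and negates the ratio
  a <- test_window(37, 81, 2e6, 1e6)
  b <- test_window(81, 37, 1e6, 2e6)
  expect_equal(a$p_enrich, b$p_deplete)
  expect_equal(a$p_deplete, b$p_enrich)
  expect_equal(a$log2_ratio, -b$log2_ratio)
  expect_error(test_window(-1, 2, 1e6, 1e6), "non-negative")
})

# deterministic fragment sets: exactly `per` midpoints per 10-kb window
.uniform_library <- function(chrom_len, per, boost = NULL, boost_per = NULL) {
  starts <- seq(0, chrom_len - 10000, by = 10000)
  mids <- unlist(lapply(seq_along(starts), function(i) {
    n <- if (!is.null(boost) && i %in% boost) boost_per else per
    starts[i] + round((seq_len(n) - 0.5) * 10000 / n)
  }))
  fragment_set(genomic_intervals("chrS", mids - 50, mids + 50))
}

test_that("a planted 8x window is called enriched and nothing else", {
  sizes <- c(chrS = 1e6)
  input <- .uniform_library(1e6, 50)
  chip <- .uniform_library(1e6, 50, boost = 43, boost_per = 400)
  rc <- call_differential_windows(chip, input, sizes)
  expect_equal(nrow(rc$enriched), 1)
  expect_equal(rc$enriched$start, 420000)
  expect_equal(rc$enriched$end, 430000)
  expect_equal(nrow(rc$depleted), 0)
  # input 8x chip: the same region is called depleted only
  rc2 <- call_differential_windows(input, chip, sizes)
  expect_equal(rc2$depleted[, c("chrom", "start", "end")],
               rc$enriched[, c("chrom", "start", "end")])
  expect_equal(nrow(rc2$enriched), 0)
})

test_that("identical libraries yield no calls and adjacent windows merge", {
  sizes <- c(chrS = 5e5)
  lib <- .uniform_library(5e5, 60)
  rc <- call_differential_windows(lib, lib, sizes)
  expect_equal(nrow(rc$enriched) + nrow(rc$depleted), 0)
  # two adjacent boosted windows merge into one region
  chip <- .uniform_library(5e5, 60, boost = c(20, 21), boost_per = 480)
  rc2 <- call_differential_windows(chip, lib, sizes)
  expect_equal(nrow(rc2$enriched), 1)
  expect_equal(rc2$enriched$end - rc2$enriched$start, 20000)
  expect_error(call_differential_windows(chip, lib, sizes, window_bp = 0), "window_bp")
  expect_error(call_differential_windows(chip, lib, sizes, step_bp = -1), "step_bp")
})

test_that("swapping chip and input exactly exchanges the call sets", {
  cfg <- small_cfg(seed = 9)
  u <- simulate_uhrf1(cfg)
  fwd <- call_differential_windows(u$chip, u$input, u$chrom_sizes)
  rev <- call_differential_windows(u$input, u$chip, u$chrom_sizes)
  expect_equal(fwd$enriched[, c("chrom", "start", "end")],
               rev$depleted[, c("chrom", "start", "end")])
  expect_equal(fwd$depleted[, c("chrom", "start", "end")],
               rev$enriched[, c("chrom", "start", "end")])
})

test_that("region annotation applies promoter > gene body > intergenic precedence", {
  genes <- genomic_intervals("chr1", c(10000, 50000), c(20000, 60000),
                             name = c("gA", "gB"))
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    strand = "+", tss = c(10000, 50000))
  regions <- genomic_intervals("chr1",
                               c(15000, 9000, 80000, 49000),
                               c(16000, 9500, 81000, 52000))
  ann <- annotate_regions(regions, genes, tss)
  expect_equal(as.character(ann$regions$category),
               c("gene_body", "promoter", "intergenic", "promoter"))
  expect_equal(sum(ann$tally$fraction), 1)
  # chromosome with no annotation at all -> intergenic
  lonely <- annotate_regions(genomic_intervals("chrZ", 0, 100), genes, tss)
  expect_equal(as.character(lonely$regions$category), "intergenic")
})
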