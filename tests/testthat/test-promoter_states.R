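test_that("promoter windows use mark-specific half-widths around the TSS", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000, 1000))
  lib <- fragment_set(genomic_intervals("chr1", 9000, 9200))
  k4 <- quantify_promoters(lib, lib, tss, "H3K4me3")
  expect_equal(k4$start[1], 8000)
  expect_equal(k4$end[1], 12000)
  k27 <- quantify_promoters(lib, lib, tss, "H3K27me3")
  expect_equal(k27$start[1], 5000)
  expect_equal(k27$end[1], 15000)
  expect_equal(k27$start[2], 0)  # clipped at the chromosome start
  expect_equal(k27$end[2], 6000)
  expect_error(quantify_promoters(lib, lib, tss[0, ], "H3K4me3"), "empty TSS")
  expect_equal(mark_halfwidth("H3K4me3"), 2000)
  expect_equal(mark_halfwidth("H3K27me3"), 5000)
})

test_that("presence needs both the two-fold gate and the FDR gate", {
  # single promoter, chip 40 vs input 10 at equal depth:
  # log2((40.5)/(10.5)) = 1.948 and P(Pois(10.5) >= 40) is tiny
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 5000)
  # n fragments inside the window plus off-window background so that both
  # libraries have 1000 fragments (cpm ratio = in-window count ratio)
  mk <- function(n) {
    mids <- c(seq(4000, 5990, length.out = n), seq(20000, 80000, length.out = 1000 - n))
    fragment_set(genomic_intervals("chr1", round(mids) - 50, round(mids) + 50))
  }
  q <- quantify_promoters(mk(40), mk(10), tss, "H3K4me3")
  expect_equal(q$chip_count, 40)
  expect_equal(q$input_count, 10)
  expect_equal(q$p_value, poisson_upper_pvalue(40, (1e4 + 0.5) * 1000 / 1e6))
  expect_true(q$present)
  # high fold but weak evidence: 3 vs 1 fragments fails the FDR gate
  q2 <- quantify_promoters(mk(3), mk(1), tss, "H3K4me3")
  expect_gt(q2$log2_ratio, 1)
  expect_false(q2$present)
})

test_that("the four-state map is total with distinct outputs", {
  expect_equal(as.character(classify_promoter(TRUE, FALSE)), "active")
  expect_equal(as.character(classify_promoter(TRUE, TRUE)), "bivalent")
  expect_equal(as.character(classify_promoter(FALSE, TRUE)), "repressive")
  expect_equal(as.character(classify_promoter(FALSE, FALSE)), "no_mark")
  grid <- expand.grid(k4 = c(TRUE, FALSE), k27 = c(TRUE, FALSE))
  out <- classify_promoter(grid$k4, grid$k27)
  expect_equal(length(unique(out)), 4)
  expect_equal(levels(out), promoter_state_levels())
  expect_error(classify_promoter(NA, TRUE), "TRUE/FALSE")
})

test_that("transition tables count, percentage, and report retention correctly", {
  lv <- promoter_state_levels()
  genes <- sprintf("g%02d", 1:10)
  wt <- setNames(factor(rep("bivalent", 10), levels = lv), genes)
  ko <- setNames(factor(c(rep("active", 4), rep("bivalent", 4),
                          rep("repressive", 2)), levels = lv), genes)
  tt <- transition_table(wt, ko)
  expect_equal(sum(tt$counts), 10)
  expect_equal(unname(tt$row_pct["bivalent", ]), c(40, 40, 20, 0))
  expect_equal(unname(tt$retention["bivalent"]), 0.4)
  # empty WT classes: retention is missing, never zero
  expect_true(all(is.na(tt$retention[c("active", "repressive", "no_mark")])))
  # identical states: diagonal table, full retention
  ident <- transition_table(ko, ko)
  expect_equal(sum(diag(ident$counts)), 10)
  expect_equal(unname(ident$retention[c("active", "bivalent", "repressive")]),
               c(1, 1, 1))
  # mismatched universes name the offenders
  expect_error(transition_table(wt, ko[1:9]), "g10")
})

test_that("retention is invariant under gene relabeling", {
  lv <- promoter_state_levels()
  withr::with_seed(3, {
    wt <- setNames(factor(sample(lv, 50, TRUE), levels = lv), sprintf("a%02d", 1:50))
    ko <- setNames(factor(sample(lv, 50, TRUE), levels = lv), names(wt))
  })
  t1 <- transition_table(wt, ko)
  relabel <- setNames(sprintf("z%02d", 1:50), names(wt))
  t2 <- transition_table(setNames(wt, relabel[names(wt)]),
                         setNames(ko, relabel[names(ko)]))
  expect_equal(t1$counts, t2$counts)
  expect_equal(t1$retention, t2$retention)
})

test_that("per-class signal means separate a planted bivalent enrichment", {
  n_per <- 200
  lv <- promoter_state_levels()
  tss_pos <- (seq_len(2 * n_per)) * 5000
  tss <- data.frame(gene_id = sprintf("g%03d", seq_along(tss_pos)), chrom = "chr1",
                    strand = "+", tss = tss_pos)
  states <- data.frame(gene_id = tss$gene_id,
                       state = factor(rep(c("bivalent", "active"), each = n_per),
                                      levels = lv))
  withr::with_seed(21, {
    counts <- rpois(length(tss_pos), ifelse(states$state == "bivalent", 90, 30))
    idx <- rep(seq_along(counts), counts)
    mids <- tss$tss[idx] + round(runif(length(idx), -1500, 1500))
    frags <- fragment_set(genomic_intervals("chr1", mids - 50, mids + 50))
  })
  track <- make_binned_track(frags, c(chr1 = max(tss_pos) + 10000), 500)
  res <- suppressWarnings(signal_by_class(track, states, tss, halfwidth = 2000))
  expect_gt(res$class_means[["bivalent"]], res$class_means[["active"]])
  p_ab <- res$tests$p_value[res$tests$class_a == "active" & res$tests$class_b == "bivalent"]
  expect_lt(p_ab, 0.01)
  # classes that are absent are skipped with a warning, not an error
  expect_warning(signal_by_class(track, states, tss), "fewer than 2")
})

test_that("degenerate identical signal yields skipped tests, not fake p-values", {
  # one fragment per promoter, one promoter per bin: identical signal
  tss <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), chrom = "chr1",
                    strand = "+", tss = c(10000, 30000, 50000, 70000))
  states <- data.frame(gene_id = tss$gene_id,
                       state = factor(c("active", "active", "bivalent", "bivalent"),
                                      levels = promoter_state_levels()))
  frags <- fragment_set(genomic_intervals("chr1", tss$tss - 50, tss$tss + 50))
  track <- make_binned_track(frags, c(chr1 = 8e4), 20000)
  # one fragment per promoter: within-class variance is zero
  expect_warning(res <- signal_by_class(track, states, tss, halfwidth = 2000),
                 "zero variance|fewer than 2")
  expect_true(all(is.na(res$tests$p_value)))
})
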