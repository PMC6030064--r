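test_that("every generator is a pure function of (config, seed)", {
  cfg <- small_cfg(seed = 5)
  ann <- simulate_annotation(cfg)
  expect_identical(ann, simulate_annotation(cfg))
  st <- simulate_states(cfg, ann)
  expect_identical(st, simulate_states(cfg, ann))
  expect_identical(simulate_tf_peaks(cfg), simulate_tf_peaks(cfg))
  expect_identical(simulate_atac(cfg), simulate_atac(cfg))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_peptides(cfg), simulate_peptides(cfg))
  expect_identical(simulate_uhrf1(cfg), simulate_uhrf1(cfg))
  # a different seed changes the draws
  expect_false(identical(simulate_atac(cfg), simulate_atac(small_cfg(seed = 6))))
})

test_that("annotation respects genome bounds, density, and degenerate configs", {
  cfg <- small_cfg(seed = 2)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$tss), cfg$n_genes)
  expect_silent(validate_intervals(ann$genes))
  expect_true(all(ann$genes$end <= cfg$chromosomes[ann$genes$chrom]))
  # TSSs are farther apart than the widest promoter window (2 x 5 kb)
  by_chr <- split(ann$tss$tss, ann$tss$chrom)
  expect_true(all(unlist(lapply(by_chr, function(x) diff(sort(x)))) > 10000))
  expect_equal(nrow(simulate_annotation(sim_config(1, n_genes = 0))$tss), 0)
  expect_error(simulate_annotation(sim_config(1, n_genes = 100,
                                              chromosomes = c(chr1 = 1e5))),
               "do not fit")
})

test_that("planted marks raise the empirical ChIP/input ratio where planted", {
  cfg <- small_cfg(seed = 8)
  ann <- simulate_annotation(cfg)
  st <- simulate_states(cfg, ann)
  chip <- simulate_chip(cfg, ann, st)
  hw <- mark_halfwidth("H3K4me3")
  win <- genomic_intervals(ann$tss$chrom, pmax(0, ann$tss$tss - hw), ann$tss$tss + hw)
  cc <- count_fragments_in(chip$H3K4me3$WT$chip, win)
  ic <- count_fragments_in(chip$H3K4me3$WT$input, win)
  present <- st$wt_state %in% c("active", "bivalent")
  ratio <- (cc + 1) / (ic + 1)
  expect_gt(mean(ratio[present]), 2 * mean(ratio[!present]))
  # raw count fold at planted windows is near the configured 4x
  # (attenuated slightly by the shared uniform background)
  expect_gt(mean(cc[present]) / mean(ic[present]), 3)
  expect_lt(mean(cc[present]) / mean(ic[present]), 5)
})

test_that("a fold-1 configuration is a faithful null for the classifier", {
  cfg <- small_cfg(seed = 12, chip = list(fold = 1))
  ann <- simulate_annotation(cfg)
  st <- simulate_states(cfg, ann)
  chip <- simulate_chip(cfg, ann, st)
  q <- quantify_promoters(chip$H3K4me3$WT$chip, chip$H3K4me3$WT$input,
                          ann$tss, "H3K4me3")
  expect_lte(sum(q$present), ceiling(0.05 * nrow(q)))
})

test_that("planted TF peak sets include both overlap boundaries and exact fractions", {
  cfg <- small_cfg(seed = 4)
  tf <- simulate_tf_peaks(cfg)
  expect_equal(sum(tf$fractions), 1)
  expect_equal(unname(tf$fractions), unname(cfg$tf$fate_fractions))
  # recover WT-specific Oct4 peaks, then fates, end to end
  oct4 <- compare_peak_sets(tf$peak_sets$Oct4$WT, tf$peak_sets$Oct4$KO)
  expect_equal(nrow(oct4$a_specific), cfg$tf$n_wt_specific)
  sox2 <- compare_peak_sets(tf$peak_sets$Sox2$KO, tf$peak_sets$Sox2$WT)
  nanog <- compare_peak_sets(tf$peak_sets$Nanog$KO, tf$peak_sets$Nanog$WT)
  fates <- classify_oct4_fate(oct4$a_specific, sox2$a_specific, nanog$a_specific)
  m <- merge(tf$truth, fates$calls, by = c("chrom", "start", "end"))
  expect_equal(nrow(m), cfg$tf$n_wt_specific)
  expect_equal(as.character(m$fate.x), as.character(m$fate.y))
  # the inclusive gap-100 boundary is planted in each replacement class
  sox_truth <- tf$truth[tf$truth$fate %in% c("Sox2_replacement",
                                             "Sox2_Nanog_replacement"), ]
  min_gaps <- vapply(seq_len(nrow(sox_truth)), function(i)
    min(interval_gap(sox_truth[i, ], tf$peak_sets$Sox2$KO)), numeric(1))
  expect_true(100 %in% min_gaps)
  expect_true(all(min_gaps <= 100))
})

test_that("ATAC libraries honor the size mixture and the planted effect", {
  cfg <- small_cfg(seed = 19)
  at <- simulate_atac(cfg)
  len <- at$wt$fragments$end - at$wt$fragments$start
  phat <- mean(len < 150)
  p0 <- cfg$atac$sub150_fraction
  se <- sqrt(p0 * (1 - p0) / length(len))
  expect_lt(abs(phat - p0), 3 * se)
  # strict filter: retained set is exactly the sub-150 fragments
  kept <- filter_fragments_by_size(at$wt)
  expect_equal(kept$library_size, sum(len < 150))
  expect_true(all(kept$fragments$end - kept$fragments$start < 150))
  # zero planted effect: WT and KO in-peak signal is symmetric
  null_at <- simulate_atac(small_cfg(seed = 19, atac = list(ko_effect = 1)))
  res <- signal_in_peaks_test(filter_fragments_by_size(null_at$wt),
                              filter_fragments_by_size(null_at$ko), null_at$peaks)
  expect_lt(abs(res$summary$mean_log2_ratio), 0.15)
})

test_that("expression generator plants exact profiles and KO shifts", {
  # zero noise: relative profiles are exact
  cfg0 <- small_cfg(seed = 3, expression = list(noise_sd = 0))
  ex0 <- simulate_expression(cfg0)
  v <- ex0$em$values
  m1 <- names(ex0$truth$modules)[ex0$truth$modules == 1]
  expect_equal(unname(v[m1[1], ]), unname(v[m1[2], ]))
  # KO shift of module 1 is the configured fold at every timepoint
  wt_cols <- ex0$em$samples$condition == "WT"
  expect_equal(unname(v[m1[1], !wt_cols] / v[m1[1], wt_cols]),
               rep(ex0$truth$ko_shift_fold[1], sum(wt_cols)))
  # with noise, the planted shift appears in the sample means
  ex <- simulate_expression(small_cfg(seed = 3))
  m1 <- names(ex$truth$modules)[ex$truth$modules == 1]
  ratio <- mean(ex$em$values[m1, "KO_t1"]) / mean(ex$em$values[m1, "WT_t1"])
  expect_lt(abs(ratio - 1.5), 0.2)
})

test_that("peptide generator guarantees recoverable truth, including the empty case", {
  cfg <- small_cfg(seed = 23)
  pep <- simulate_peptides(cfg)
  res <- call_interactors(pep$bait, pep$control, background = pep$background)
  expect_setequal(res$calls$protein_id[res$calls$candidate], pep$truth)
  none <- simulate_peptides(small_cfg(seed = 23, peptides = list(n_interactors = 0)))
  expect_equal(length(none$truth), 0)
  res0 <- call_interactors(none$bait, none$control, background = none$background)
  expect_false(any(res0$calls$candidate))
})

test_that("planted enriched windows carry elevated empirical ratios", {
  cfg <- small_cfg(seed = 29)
  u <- simulate_uhrf1(cfg)
  cc <- count_fragments_in(u$chip, u$truth$enriched)
  ic <- count_fragments_in(u$input, u$truth$enriched)
  expect_gt(min((cc + 1) / (ic + 1)), 2)
  cc_d <- count_fragments_in(u$chip, u$truth$depleted)
  ic_d <- count_fragments_in(u$input, u$truth$depleted)
  expect_lt(max((cc_d + 1) / (ic_d + 1)), 0.5)
})
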