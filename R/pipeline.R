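# End-to-end driver: simulate every input from one seed, run all
# analysis stages, optionally write both the simulated data and the
# derived tables as plain-text files (deterministic given the seed).

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write all simulated inputs and truth files under a directory
#'
#' Emits fragment/peak BEDs, chrom sizes, TSS table, RPKM matrix and
#' sample sheet, peptide tables, and tab-delimited truth files. Output
#' is byte-deterministic given the configuration seed.
#'
#' @param sim output of [simulate_all()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  sub <- function(...) {
    d <- file.path(outdir, ...)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  root <- sub(".")
  write_chrom_sizes(sim$annotation$chrom_sizes, file.path(root, "chrom_sizes.tsv"))
  write_tss_table(sim$annotation$tss, file.path(root, "tss.tsv"))
  write_bed(sim$annotation$genes, file.path(root, "genes.bed"))
  d <- sub("chip")
  for (mark in names(sim$chip)) for (cond in names(sim$chip[[mark]]))
    for (channel in c("chip", "input"))
      write_bed(sim$chip[[mark]][[cond]][[channel]]$fragments,
                file.path(d, sprintf("%s_%s_%s.bed", mark, cond, channel)))
  d <- sub("tf")
  for (fac in names(sim$tf$peak_sets)) for (cond in names(sim$tf$peak_sets[[fac]]))
    write_bed(sim$tf$peak_sets[[fac]][[cond]],
              file.path(d, sprintf("%s_%s.bed", fac, cond)))
  d <- sub("atac")
  write_bed(sim$atac$wt$fragments, file.path(d, "WT.bed"))
  write_bed(sim$atac$ko$fragments, file.path(d, "KO.bed"))
  write_bed(sim$atac$peaks, file.path(d, "peaks.bed"))
  d <- sub("expression")
  rpkm <- data.frame(gene_id = rownames(sim$expression$em$values),
                     sim$expression$em$values, check.names = FALSE)
  .write_tsv(rpkm, file.path(d, "rpkm.tsv"))
  .write_tsv(sim$expression$em$samples, file.path(d, "samples.tsv"))
  d <- sub("peptides")
  for (r in seq_along(sim$peptides$bait)) {
    .write_tsv(sim$peptides$bait[[r]]$counts, file.path(d, sprintf("bait_rep%d.tsv", r)))
    .write_tsv(sim$peptides$control[[r]]$counts, file.path(d, sprintf("control_rep%d.tsv", r)))
  }
  writeLines(sim$peptides$background, file.path(d, "background.txt"))
  d <- sub("uhrf1")
  write_chrom_sizes(sim$uhrf1$chrom_sizes, file.path(d, "chrom_sizes.tsv"))
  write_bed(sim$uhrf1$chip$fragments, file.path(d, "chip.bed"))
  write_bed(sim$uhrf1$input$fragments, file.path(d, "input.bed"))
  d <- sub("truth")
  .write_tsv(sim$states, file.path(d, "states.tsv"))
  .write_tsv(sim$tf$truth, file.path(d, "tf_fates.tsv"))
  .write_tsv(data.frame(gene_id = names(sim$expression$truth$modules),
                        module = sim$expression$truth$modules),
             file.path(d, "modules.tsv"))
  writeLines(sim$peptides$truth, file.path(d, "interactors.txt"))
  write_bed(sim$uhrf1$truth$enriched, file.path(d, "uhrf1_enriched.bed"))
  write_bed(sim$uhrf1$truth$depleted, file.path(d, "uhrf1_depleted.bed"))
  .write_tsv(data.frame(ko_effect = sim$atac$truth$ko_effect,
                        sub150_fraction = sim$atac$truth$sub150_fraction,
                        peak_depth = sim$atac$truth$peak_depth),
             file.path(d, "atac.tsv"))
  invisible(outdir)
}

#' Run the full analysis pipeline on simulated data
#'
#' Generates every input from `cfg`, then runs all stages: promoter
#' quantification and four-state classification in WT and KO with the
#' WT-to-KO transition table; enriched/depleted region calling on the
#' planted ChIP/input pair with genic annotation; Oct4 binding-fate
#' classification against KO-specific Sox2/Nanog peaks; ATAC sub-150 bp
#' filtering and in-peak WT/KO comparison; dynamic-gene filtering,
#' module clustering, profiles and WT/KO significance flags; and AP-MS
#' interactor calling.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory; when given, simulated inputs and
#'   all result tables are written there (deterministic per seed).
#' @return list with `sim` and one element per analysis stage.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = NULL) {
  sim <- simulate_all(cfg)
  tss <- sim$annotation$tss

  states_called <- lapply(c(WT = "WT", KO = "KO"), function(cond) {
    k4 <- quantify_promoters(sim$chip$H3K4me3[[cond]]$chip,
                             sim$chip$H3K4me3[[cond]]$input, tss, "H3K4me3")
    k27 <- quantify_promoters(sim$chip$H3K27me3[[cond]]$chip,
                              sim$chip$H3K27me3[[cond]]$input, tss, "H3K27me3")
    promoter_states(k4, k27)
  })
  transitions <- transition_table(states_called$WT, states_called$KO)

  regions <- call_differential_windows(sim$uhrf1$chip, sim$uhrf1$input,
                                       sim$uhrf1$chrom_sizes)
  region_annotation <- annotate_regions(regions$enriched, sim$annotation$genes, tss)

  oct4 <- compare_peak_sets(sim$tf$peak_sets$Oct4$WT, sim$tf$peak_sets$Oct4$KO)
  sox2 <- compare_peak_sets(sim$tf$peak_sets$Sox2$KO, sim$tf$peak_sets$Sox2$WT)
  nanog <- compare_peak_sets(sim$tf$peak_sets$Nanog$KO, sim$tf$peak_sets$Nanog$WT)
  fates <- classify_oct4_fate(oct4$a_specific, sox2$a_specific, nanog$a_specific,
                              tss = tss)

  atac_wt <- filter_fragments_by_size(sim$atac$wt)
  atac_ko <- filter_fragments_by_size(sim$atac$ko)
  atac <- signal_in_peaks_test(atac_wt, atac_ko, sim$atac$peaks)

  em <- sim$expression$em
  ss <- em$samples[em$samples$condition == "WT", ]
  ref <- ss$sample[which.min(ss$timepoint)]
  dynamic <- filter_dynamic_genes(em, ref)
  modules <- cluster_modules(em, genes = dynamic)
  profiles <- module_profiles(modules, em, ref)
  significance <- module_significance(modules, em)

  interactome <- call_interactors(sim$peptides$bait, sim$peptides$control,
                                  background = sim$peptides$background)

  res <- list(sim = sim,
              states = states_called,
              transitions = transitions,
              regions = regions,
              region_annotation = region_annotation,
              tf = list(oct4_wt_specific = oct4$a_specific, fates = fates),
              atac = atac,
              modules = list(reference_sample = ref, dynamic_genes = dynamic,
                             assignment = modules, profiles = profiles,
                             significance = significance),
              interactome = interactome)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write all derived result tables of a pipeline run
#'
#' @param res output of [run_pipeline()].
#' @param outdir directory (created if needed); simulated inputs go to
#'   `outdir/sim`, result tables to `outdir/results`.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  write_simulation(res$sim, file.path(outdir, "sim"))
  d <- file.path(outdir, "results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(res$states$WT, file.path(d, "promoter_states_WT.tsv"))
  .write_tsv(res$states$KO, file.path(d, "promoter_states_KO.tsv"))
  cnt <- data.frame(wt_state = rownames(res$transitions$counts),
                    res$transitions$counts, check.names = FALSE)
  .write_tsv(cnt, file.path(d, "transition_counts.tsv"))
  pct <- data.frame(wt_state = rownames(res$transitions$row_pct),
                    round(res$transitions$row_pct, 4), check.names = FALSE)
  .write_tsv(pct, file.path(d, "transition_row_pct.tsv"))
  .write_tsv(data.frame(state = names(res$transitions$retention),
                        retention = round(res$transitions$retention, 6)),
             file.path(d, "retention.tsv"))
  write_bed(res$regions$enriched, file.path(d, "uhrf1_enriched.bed"))
  write_bed(res$regions$depleted, file.path(d, "uhrf1_depleted.bed"))
  .write_tsv(res$regions$windows, file.path(d, "uhrf1_windows.tsv"))
  .write_tsv(res$region_annotation$tally, file.path(d, "region_annotation.tsv"))
  .write_tsv(res$tf$fates$calls, file.path(d, "tf_fates.tsv"))
  .write_tsv(data.frame(fate = names(res$tf$fates$fractions),
                        fraction = res$tf$fates$fractions),
             file.path(d, "tf_fate_fractions.tsv"))
  .write_tsv(res$atac$per_peak, file.path(d, "atac_per_peak.tsv"))
  .write_tsv(as.data.frame(res$atac$summary), file.path(d, "atac_summary.tsv"))
  .write_tsv(data.frame(gene_id = names(res$modules$assignment$modules),
                        module = res$modules$assignment$modules),
             file.path(d, "module_assignment.tsv"))
  .write_tsv(res$modules$profiles, file.path(d, "module_profiles.tsv"))
  .write_tsv(res$modules$significance, file.path(d, "module_significance.tsv"))
  .write_tsv(res$interactome$calls, file.path(d, "interactome_calls.tsv"))
  invisible(outdir)
}
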