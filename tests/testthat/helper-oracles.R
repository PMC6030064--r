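# Independent oracles and small simulation configurations shared by the
# test files. The oracles deliberately avoid the code paths they check.

# upper-tail Poisson probability by direct pmf summation (no ppois)
oracle_pois_tail <- function(k, lam) {
  if (k == 0) return(1)
  j <- 0:(k - 1)
  1 - sum(exp(j * log(lam) - lam - lgamma(j + 1)))
}

# explicit BH step-up, written independently of bh_adjust()
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    js <- i:n
    q_sorted[i] <- min(p[o][js] * n / js, 1)
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# base-level recall/precision of called vs true regions
region_overlap_stats <- function(called, truth) {
  gr_c <- GenomicRanges::reduce(GenomicRanges::GRanges(
    called$chrom, IRanges::IRanges(called$start + 1, called$end)))
  gr_t <- GenomicRanges::reduce(GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1, truth$end)))
  inter <- sum(IRanges::width(suppressWarnings(GenomicRanges::intersect(gr_c, gr_t))))
  list(recall = inter / sum(IRanges::width(gr_t)),
       precision = if (sum(IRanges::width(gr_c)) == 0) NA_real_
                   else inter / sum(IRanges::width(gr_c)))
}

# reduced-scale configuration for fast unit tests (the acceptance suite
# uses the full defaults)
small_cfg <- function(seed = 1, ...) {
  sim_config(seed,
             chromosomes = c(chr1 = 3e7, chr2 = 3e7),
             n_genes = 200,
             chip = list(bg_fragments = 1e5),
             tf = list(n_shared = 20, n_wt_specific = 40, n_decoys = 10),
             atac = list(n_peaks = 100, bg_fragments = 5e4),
             expression = list(genes_per_module = 40),
             peptides = list(n_proteins = 80, n_interactors = 8,
                             n_background = 10),
             uhrf1 = list(chromosomes = c(chrE1 = 2e6, chrE2 = 2e6),
                          n_enriched = 4, n_depleted = 4),
             ...)
}

apms_fixture_path <- function(file) {
  system.file("extdata", "apms", file, package = "chromstates", mustWork = TRUE)
}

read_apms_fixture <- function() {
  list(bait = list(read_peptide_table(apms_fixture_path("bait_rep1.tsv"), "bait", "rep1"),
                   read_peptide_table(apms_fixture_path("bait_rep2.tsv"), "bait", "rep2")),
       control = list(read_peptide_table(apms_fixture_path("control_rep1.tsv"), "control", "rep1"),
                      read_peptide_table(apms_fixture_path("control_rep2.tsv"), "control", "rep2")),
       background = readLines(apms_fixture_path("background.txt")))
}
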