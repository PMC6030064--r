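#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input from one seed and write the
# data plus planted-truth files. All downstream stages regenerate the
# pieces they need from the same configuration (the generators are pure
# functions of the seed), so the stages can be run independently.

suppressPackageStartupMessages(library(chromstates))

cfg <- sim_config(seed = 1)
sim <- simulate_all(cfg)
write_simulation(sim, "results/sim")

cat(sprintf("genome: %s\n", paste(sprintf("%s=%d", names(cfg$chromosomes),
                                          as.integer(cfg$chromosomes)), collapse = " ")))
cat(sprintf("genes: %d; WT state mix: %s\n", nrow(sim$annotation$tss),
            paste(capture.output(print(table(sim$states$wt_state)))[-1], collapse = " ")))
cat(sprintf("ChIP libraries: %d (2 marks x 2 conditions x chip/input)\n",
            2 * 2 * 2))
cat(sprintf("TF peaks: %d shared + %d WT-specific Oct4 (planted fates: %s)\n",
            cfg$tf$n_shared, cfg$tf$n_wt_specific,
            paste(sprintf("%s=%.2f", names(sim$tf$fractions), sim$tf$fractions),
                  collapse = " ")))
cat(sprintf("ATAC: %d peaks, planted KO effect %.2f, sub-150 fraction %.2f\n",
            cfg$atac$n_peaks, cfg$atac$ko_effect, cfg$atac$sub150_fraction))
cat(sprintf("expression: %d modules x %d genes; AP-MS: %d proteins, %d planted interactors\n",
            cfg$expression$n_modules, cfg$expression$genes_per_module,
            cfg$peptides$n_proteins, cfg$peptides$n_interactors))
cat("wrote results/sim/\n")
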