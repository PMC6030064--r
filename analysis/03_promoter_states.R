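#!/usr/bin/env Rscript
# Stage 3: quantify H3K4me3 (+/-2 kb) and H3K27me3 (+/-5 kb) at every
# promoter in WT and KO, classify the four states, and measure the
# WT -> KO transition table and retention rates against planted truth.

suppressPackageStartupMessages(library(chromstates))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
ann <- simulate_annotation(cfg)
st <- simulate_states(cfg, ann)
chip <- simulate_chip(cfg, ann, st)

called <- lapply(c(WT = "WT", KO = "KO"), function(cond) {
  k4 <- quantify_promoters(chip$H3K4me3[[cond]]$chip,
                           chip$H3K4me3[[cond]]$input, ann$tss, "H3K4me3")
  k27 <- quantify_promoters(chip$H3K27me3[[cond]]$chip,
                            chip$H3K27me3[[cond]]$input, ann$tss, "H3K27me3")
  promoter_states(k4, k27)
})

acc <- c(WT = mean(as.character(called$WT$state) == as.character(st$wt_state)),
         KO = mean(as.character(called$KO$state) == as.character(st$ko_state)))
cat(sprintf("per-gene state accuracy: WT %.1f%%, KO %.1f%%\n",
            100 * acc["WT"], 100 * acc["KO"]))

tt <- transition_table(called$WT, called$KO)
print(tt)
planted <- transition_table(setNames(st$wt_state, st$gene_id),
                            setNames(st$ko_state, st$gene_id))
cat(sprintf("max |row%% - planted|: %.2f points; max |retention - planted|: %.4f\n",
            max(abs(tt$row_pct - planted$row_pct), na.rm = TRUE),
            max(abs(tt$retention - planted$retention), na.rm = TRUE)))

for (cond in c("WT", "KO"))
  write.table(called[[cond]], sprintf("results/promoter_states_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(wt_state = rownames(tt$row_pct), round(tt$row_pct, 2)),
            "results/transition_row_pct.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
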