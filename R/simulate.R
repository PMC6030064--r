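# Seeded generators for every input the pipeline consumes, with planted
# ground truth returned alongside. One global seed expands into fixed
# per-generator substreams (seed + offset) so changing one component's
# parameters never perturbs another's draws.

.STREAM <- c(annotation = 101, states = 211, chip = 307, tf = 401,
             atac = 503, expression = 601, peptides = 701, uhrf1 = 809)

#' Default planted WT to KO promoter-state transition matrix
#'
#' Rows (WT state) sum to 1. The bivalent row encodes 45% retention with
#' redistribution 33.57% to active and 13.95% to repressive; the
#' repressive row sends 50.4% to no-mark; active and no-mark promoters
#' are mostly retained.
#'
#' @return 4x4 row-stochastic matrix over the promoter states.
#' @export
default_transition_matrix <- function() {
  lv <- promoter_state_levels()
  m <- rbind(
    active     = c(0.90,   0.02, 0.02,   0.06),
    bivalent   = c(0.3357, 0.45, 0.1395, 0.0748),
    repressive = c(0.03,   0.02, 0.446,  0.504),
    no_mark    = c(0.04,   0.01, 0.03,   0.92))
  dimnames(m) <- list(lv, lv)
  m
}

# internal: recursive modifyList for nested config overrides; iterates
# by position so repeated names (e.g. chip = ... given twice) apply in
# order instead of the first silently winning
.merge_cfg <- function(base, override) {
  for (i in seq_along(override)) {
    nm <- names(override)[i]
    if (is.list(base[[nm]]) && is.list(override[[i]]))
      base[[nm]] <- .merge_cfg(base[[nm]], override[[i]])
    else base[[nm]] <- override[[i]]
  }
  base
}

#' Simulation configuration with planted-truth defaults
#'
#' Defaults encode the conditions the pipeline is specified to handle:
#' 2,000 genes, 4-fold ChIP enrichment over a mean of 50 input fragments
#' per promoter window, the default planted transition matrix, TF peak
#' fate fractions (0.4 loss / 0.3 Sox2 / 0.2 Nanog / 0.1 both), ATAC
#' sub-150 bp mixtures with a planted 50% in-peak KO depletion, 4
#' expression modules x 100 genes at 2 log2-unit separation and noise SD
#' 0.3, and an AP-MS design with planted interactors. Chromosome sizes
#' default to 2 x 500 Mb so that promoters sit far apart relative to the
#' widest quantification window and the uniform background dominates
#' every library (promoter fragments are ~16% of the ChIP library, as in
#' real ChIP-seq); that keeps ChIP and input library sizes comparable so
#' the planted fold survives CPM normalization with a wide margin.
#'
#' @param seed integer master seed.
#' @param ... nested overrides, e.g. `chip = list(fold = 1)`.
#' @return a list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chromosomes = c(chr1 = 5e8, chr2 = 5e8),
    n_genes = 2000,
    state_probs_wt = c(active = 0.40, bivalent = 0.25,
                       repressive = 0.15, no_mark = 0.20),
    transition = default_transition_matrix(),
    chip = list(fold = 4, input_mean = 50, bg_fragments = 1.5e6,
                fragment_bp = 200),
    tf = list(n_shared = 100, n_wt_specific = 200, n_decoys = 50,
              peak_bp = 200, slot_bp = 5000,
              fate_fractions = c(loss = 0.4, Sox2_replacement = 0.3,
                                 Nanog_replacement = 0.2,
                                 Sox2_Nanog_replacement = 0.1)),
    atac = list(n_peaks = 300, peak_bp = 500, peak_depth = 30,
                ko_effect = 0.5, sub150_fraction = 0.6,
                bg_fragments = 2e5,
                sub_len = c(mean = 80, sd = 25),
                supra_len = c(mean = 220, sd = 40)),
    expression = list(n_modules = 4, genes_per_module = 100,
                      timepoints = c(0, 1, 2, 3), separation = 2,
                      noise_sd = 0.3, base_log2 = 5,
                      ko_shift_fold = c(1.5, 1.5, 1, 1)),
    peptides = list(n_proteins = 300, n_interactors = 20,
                    n_background = 25, n_replicates = 2,
                    mean_peptides = 4),
    uhrf1 = list(chromosomes = c(chrE1 = 5e6, chrE2 = 5e6),
                 n_enriched = 30, n_depleted = 30, region_bp = 10000,
                 fold = 8, window_mean = 100, fragment_bp = 200)
  )
  cfg <- .merge_cfg(cfg, list(...))
  if (abs(sum(cfg$state_probs_wt) - 1) > 1e-8) .fail("state_probs_wt must sum to 1")
  if (any(abs(rowSums(cfg$transition) - 1) > 1e-8)) .fail("transition rows must sum to 1")
  if (abs(sum(cfg$tf$fate_fractions) - 1) > 1e-8) .fail("fate_fractions must sum to 1")
  structure(cfg, class = "SimulationConfig")
}

# internal: fragments from midpoints, clamped inside the chromosome
.frags_from_mids <- function(chrom, mids, chrom_sizes, width, library_id) {
  half <- floor(width / 2)
  size <- chrom_sizes[chrom]
  mids <- pmin(pmax(mids, half), size - (width - half) - 1)
  fragment_set(data.frame(chrom = chrom,
                          start = floor(mids) - half,
                          end = floor(mids) - half + width,
                          stringsAsFactors = FALSE),
               library_id = library_id)
}

#' Simulate a genome annotation
#'
#' Places `n_genes` on a regular per-chromosome grid with small jitter
#' (so promoter windows of neighbouring genes never overlap at the
#' default density), random strand, and non-overlapping gene bodies
#' extending 2-8 kb downstream of the TSS.
#'
#' @param cfg a [sim_config()].
#' @return list with `chrom_sizes`, `tss` (annotation table), `genes`
#'   (gene-body interval data.frame).
#' @export
simulate_annotation <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["annotation"]], {
    sizes <- cfg$chromosomes
    n <- cfg$n_genes
    empty <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss = numeric(),
                        stringsAsFactors = FALSE)
    if (n == 0) {
      return(list(chrom_sizes = sizes, tss = empty,
                  genes = genomic_intervals(character(), numeric(), numeric())))
    }
    n_per <- setNames(pmax(1, round(n * sizes / sum(sizes))), names(sizes))
    n_per[1] <- n_per[1] + (n - sum(n_per))
    spacing <- sizes / n_per
    if (any(spacing < 4000)) .fail("requested genes do not fit the genome")
    rows <- lapply(names(sizes), function(ch) {
      k <- n_per[[ch]]
      jit <- min(2000, spacing[[ch]] / 8)
      tss <- round((seq_len(k) - 0.5) * spacing[[ch]] + runif(k, -jit, jit))
      data.frame(chrom = ch, tss = pmin(pmax(tss, 0), sizes[[ch]] - 1),
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    ann$gene_id <- sprintf("g%05d", seq_len(nrow(ann)))
    body <- round(runif(nrow(ann), 2000,
                        pmin(8000, spacing[ann$chrom] * 0.4)))
    start <- ifelse(ann$strand == "+", ann$tss, ann$tss - body)
    start <- pmax(0, start)
    end <- pmin(start + body, cfg$chromosomes[ann$chrom])
    genes <- genomic_intervals(ann$chrom, start, end, strand = ann$strand,
                               name = ann$gene_id)
    list(chrom_sizes = sizes,
         tss = ann[, c("gene_id", "chrom", "strand", "tss")],
         genes = genes)
  })
}

#' Draw planted WT and KO promoter states
#'
#' WT states are sampled from `state_probs_wt`; KO states follow the
#' planted transition matrix row of each gene's WT state.
#'
#' @param cfg a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return data.frame `gene_id`, `wt_state`, `ko_state`.
#' @export
simulate_states <- function(cfg, annotation) {
  withr::with_seed(cfg$seed + .STREAM[["states"]], {
    lv <- promoter_state_levels()
    n <- nrow(annotation$tss)
    wt <- sample(lv, n, replace = TRUE, prob = cfg$state_probs_wt[lv])
    ko <- vapply(wt, function(s) sample(lv, 1, prob = cfg$transition[s, ]), "")
    data.frame(gene_id = annotation$tss$gene_id,
               wt_state = factor(wt, levels = lv),
               ko_state = factor(ko, levels = lv),
               stringsAsFactors = FALSE)
  })
}

# internal: does a state carry the mark?
.mark_present <- function(state, mark) {
  if (mark == "H3K4me3") state %in% c("active", "bivalent")
  else state %in% c("bivalent", "repressive")
}

#' Simulate ChIP and input fragment libraries for both marks and conditions
#'
#' Per promoter window (mark-specific half-width), the input count is
#' Poisson(`input_mean`) and the ChIP count Poisson(`input_mean x fold`)
#' when the mark is planted present, else Poisson(`input_mean`);
#' fragment midpoints are uniform within the window. A genome-wide
#' uniform background of `bg_fragments` expected fragments is added to
#' every library so that library sizes stay comparable between ChIP and
#' input under CPM normalization.
#'
#' @param cfg a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param states output of [simulate_states()].
#' @return nested list `[[mark]][[condition]]` with elements `chip` and
#'   `input` ([fragment_set()]s).
#' @export
simulate_chip <- function(cfg, annotation, states) {
  withr::with_seed(cfg$seed + .STREAM[["chip"]], {
    sizes <- cfg$chromosomes
    cp <- cfg$chip
    out <- list()
    for (mark in c("H3K4me3", "H3K27me3")) {
      hw <- mark_halfwidth(mark)
      win_start <- pmax(0, annotation$tss$tss - hw)
      win_end <- pmin(annotation$tss$tss + hw, sizes[annotation$tss$chrom])
      win_chrom <- annotation$tss$chrom
      out[[mark]] <- list()
      for (cond in c("WT", "KO")) {
        st <- if (cond == "WT") states$wt_state else states$ko_state
        present <- .mark_present(as.character(st), mark)
        for (channel in c("chip", "input")) {
          rate <- if (channel == "chip")
            cp$input_mean * ifelse(present, cp$fold, 1) else
            rep(cp$input_mean, length(present))
          counts <- rpois(length(rate), rate)
          idx <- rep(seq_along(counts), counts)
          sig_chrom <- win_chrom[idx]
          sig_mid <- win_start[idx] +
            floor(runif(length(idx)) * (win_end[idx] - win_start[idx]))
          n_bg <- rpois(1, cp$bg_fragments)
          bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                             prob = sizes / sum(sizes))
          bg_mid <- floor(runif(n_bg) * sizes[bg_chrom])
          fs <- .frags_from_mids(c(sig_chrom, bg_chrom), c(sig_mid, bg_mid),
                                 sizes, cp$fragment_bp,
                                 sprintf("%s_%s_%s", mark, cond, channel))
          out[[mark]][[cond]][[channel]] <- fs
        }
      }
    }
    out
  })
}

#' Simulate Oct4/Sox2/Nanog peak sets with planted binding fates
#'
#' Peaks occupy well-separated slots along the first chromosome. Shared
#' peaks go into every factor/condition set; each WT-specific Oct4 peak
#' is planted with a fate: replacement fates gain KO-specific Sox2
#' and/or Nanog peaks at edge-to-edge gaps cycling through
#' \{0, 37, 100\} bp (100 is the inclusive boundary of the overlap
#' rule), loss peaks gain nothing within the tolerance -- except one
#' designated loss peak that gets a Sox2 peak at gap exactly 101 bp, a
#' planted negative boundary case. KO-specific decoy peaks far from any
#' Oct4 peak are added to Sox2 and Nanog.
#'
#' @param cfg a [sim_config()].
#' @return list with `peak_sets` (`[[factor]][[condition]]` interval
#'   data.frames), `truth` (WT-specific Oct4 peaks with planted
#'   `fate`), `fractions` (planted fate fractions).
#' @export
simulate_tf_peaks <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["tf"]], {
    tf <- cfg$tf
    ch <- names(cfg$chromosomes)[1]
    w <- tf$peak_bp
    n_slots <- tf$n_shared + tf$n_wt_specific + 2 * tf$n_decoys + 2
    if (n_slots * tf$slot_bp + 1e5 > cfg$chromosomes[[1]])
      .fail("peak slots do not fit the first chromosome")
    slot_start <- 5e4 + (seq_len(n_slots) - 1) * tf$slot_bp
    peak_at <- function(s) data.frame(chrom = ch, start = s, end = s + w,
                                      stringsAsFactors = FALSE)
    i <- 0
    take <- function(k) { s <- slot_start[i + seq_len(k)]; i <<- i + k; s }
    shared <- peak_at(take(tf$n_shared))
    oct4_wt_sp <- peak_at(take(tf$n_wt_specific))
    counts <- round(tf$fate_fractions * tf$n_wt_specific)
    counts[1] <- counts[1] + (tf$n_wt_specific - sum(counts))
    fate <- sample(rep(fate_levels(), counts))
    # edge-to-edge gaps cycle within each replacement class so the
    # inclusive boundary (gap exactly 100) is always exercised
    gaps_for <- function(n) c(0, 37, 100)[(seq_len(n) - 1) %% 3 + 1]
    right_of <- function(p, g) data.frame(chrom = p$chrom, start = p$end + g,
                                          end = p$end + g + w)
    left_of <- function(p, g) data.frame(chrom = p$chrom, start = p$start - g - w,
                                         end = p$start - g)
    s_idx <- fate %in% c("Sox2_replacement", "Sox2_Nanog_replacement")
    n_idx <- fate %in% c("Nanog_replacement", "Sox2_Nanog_replacement")
    sox2_new <- right_of(oct4_wt_sp[s_idx, ], gaps_for(sum(s_idx)))
    nanog_new <- left_of(oct4_wt_sp[n_idx, ], gaps_for(sum(n_idx)))
    # negative boundary case: Sox2 peak at gap exactly 101 from a loss peak
    loss_i <- which(fate == "loss")[1]
    boundary <- if (!is.na(loss_i)) right_of(oct4_wt_sp[loss_i, ], 101) else NULL
    sox2_decoy <- peak_at(take(tf$n_decoys))
    nanog_decoy <- peak_at(take(tf$n_decoys))
    rb <- function(...) { x <- do.call(rbind, Filter(NROW, list(...))); rownames(x) <- NULL; x }
    peak_sets <- list(
      Oct4 = list(WT = rb(shared, oct4_wt_sp), KO = rb(shared)),
      Sox2 = list(WT = rb(shared), KO = rb(shared, sox2_new, boundary, sox2_decoy)),
      Nanog = list(WT = rb(shared), KO = rb(shared, nanog_new, nanog_decoy)))
    truth <- cbind(oct4_wt_sp, fate = factor(fate, levels = fate_levels()))
    fractions <- counts / tf$n_wt_specific
    list(peak_sets = peak_sets, truth = truth, fractions = fractions)
  })
}

#' Simulate ATAC fragment libraries with a planted in-peak KO effect
#'
#' Fragment lengths follow a two-component normal mixture (sub-150 bp
#' nucleosome-free vs 150+ bp mono-nucleosomal, truncated to
#' \[20, 149\] and \[150, 500\]); both components share the configured
#' sub-150 fraction. In-peak fragment rates in KO are scaled by the
#' planted `ko_effect` (0.5 = 50% depletion); the genome-wide background
#' is identical between conditions.
#'
#' @param cfg a [sim_config()].
#' @return list with `wt`, `ko` ([fragment_set()]s), `peaks` (interval
#'   data.frame) and `truth` (planted effect and mixture fraction).
#' @export
simulate_atac <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["atac"]], {
    at <- cfg$atac
    sizes <- cfg$chromosomes
    ch <- names(sizes)[length(sizes)]
    starts <- 1e4 + (seq_len(at$n_peaks) - 1) * 5000
    peaks <- data.frame(chrom = ch, start = starts, end = starts + at$peak_bp,
                        stringsAsFactors = FALSE)
    draw_lengths <- function(n, sub) {
      if (sub) pmin(pmax(round(rnorm(n, at$sub_len[["mean"]], at$sub_len[["sd"]])), 20), 149)
      else pmin(pmax(round(rnorm(n, at$supra_len[["mean"]], at$supra_len[["sd"]])), 150), 500)
    }
    make_lib <- function(cond) {
      mult <- if (cond == "KO") at$ko_effect else 1
      sf <- at$sub150_fraction
      n_sub <- rpois(at$n_peaks, at$peak_depth * mult)
      n_sup <- rpois(at$n_peaks, at$peak_depth * (1 - sf) / sf * mult)
      idx <- c(rep(seq_len(at$n_peaks), n_sub), rep(seq_len(at$n_peaks), n_sup))
      is_sub <- rep(c(TRUE, FALSE), c(sum(n_sub), sum(n_sup)))
      mid <- peaks$start[idx] + floor(runif(length(idx)) * at$peak_bp)
      chrom <- rep(ch, length(idx))
      n_bg <- rpois(1, at$bg_fragments)
      bg_sub <- runif(n_bg) < sf
      bg_chrom <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes / sum(sizes))
      bg_mid <- floor(runif(n_bg) * sizes[bg_chrom])
      mid <- c(mid, bg_mid); chrom <- c(chrom, bg_chrom); is_sub <- c(is_sub, bg_sub)
      len <- integer(length(mid))
      len[is_sub] <- draw_lengths(sum(is_sub), TRUE)
      len[!is_sub] <- draw_lengths(sum(!is_sub), FALSE)
      half <- len %/% 2
      start <- pmax(0, floor(mid) - half)
      end <- pmin(start + len, sizes[chrom])
      fragment_set(data.frame(chrom = chrom, start = start, end = end,
                              stringsAsFactors = FALSE),
                   library_id = sprintf("ATAC_%s", cond))
    }
    list(wt = make_lib("WT"), ko = make_lib("KO"), peaks = peaks,
         truth = list(ko_effect = at$ko_effect,
                      sub150_fraction = at$sub150_fraction,
                      peak_depth = at$peak_depth))
  })
}

#' Simulate a time-course expression matrix with planted modules
#'
#' Module mean log2-RPKM profiles follow distinct temporal patterns
#' (rising, falling, transient, dip, ...) scaled by `separation`;
#' per-gene, per-sample log-normal noise with SD `noise_sd` (log2 scale)
#' is added. KO samples of module *m* are shifted by
#' `ko_shift_fold[m]` at every timepoint.
#'
#' @param cfg a [sim_config()].
#' @return list with `em` (an [expression_matrix()]) and `truth`
#'   (planted module labels and KO shifts).
#' @export
simulate_expression <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["expression"]], {
    ex <- cfg$expression
    tp <- ex$timepoints
    nt <- length(tp)
    u <- seq(0, 1, length.out = nt)
    base_patterns <- list(u, rev(u), pmin(2 * u, 2 * (1 - u)),
                          1 - pmin(2 * u, 2 * (1 - u)),
                          rep(c(0, 1), length.out = nt),
                          rep(c(1, 0), length.out = nt))
    if (ex$n_modules > length(base_patterns)) .fail("at most %d modules supported",
                                                    length(base_patterns))
    shifts <- rep_len(ex$ko_shift_fold, ex$n_modules)
    genes <- sprintf("mod%d_g%03d", rep(seq_len(ex$n_modules), each = ex$genes_per_module),
                     rep(seq_len(ex$genes_per_module), ex$n_modules))
    samples <- expand.grid(timepoint = tp, condition = c("WT", "KO"),
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_t%g", samples$condition, samples$timepoint)
    values <- matrix(0, length(genes), nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (m in seq_len(ex$n_modules)) {
      prof <- ex$base_log2 + ex$separation * base_patterns[[m]]
      rows <- which(rep(seq_len(ex$n_modules), each = ex$genes_per_module) == m)
      for (j in seq_len(nrow(samples))) {
        mu <- prof[match(samples$timepoint[j], tp)] +
          if (samples$condition[j] == "KO") log2(shifts[m]) else 0
        values[rows, j] <- 2^(mu + rnorm(length(rows), 0, ex$noise_sd))
      }
    }
    em <- expression_matrix(values, samples[, c("sample", "condition", "timepoint")])
    truth <- list(modules = setNames(rep(seq_len(ex$n_modules),
                                         each = ex$genes_per_module), genes),
                  ko_shift_fold = shifts)
    list(em = em, truth = truth)
  })
}

#' Simulate AP-MS peptide tables with planted interactors
#'
#' Every protein gets a base abundance; controls draw Poisson counts
#' around it. Planted interactors receive a guaranteed >= 3x count
#' excess in bait replicate 1 (and background-level counts elsewhere, so
#' the "at least one replicate" rule is exercised); decoys and common
#' background proteins are clamped below 1.5x the fold-2 calling
#' threshold so the planted truth is exactly recoverable.
#'
#' @param cfg a [sim_config()].
#' @return list with `bait`, `control` (lists of [peptide_table()]s),
#'   `background` (background protein ids) and `truth` (planted
#'   interactor ids).
#' @export
simulate_peptides <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["peptides"]], {
    pp <- cfg$peptides
    n_dec <- pp$n_proteins - pp$n_interactors - pp$n_background
    if (n_dec < 0) .fail("n_proteins too small")
    ids <- c(if (pp$n_interactors) sprintf("INT%02d", seq_len(pp$n_interactors)),
             if (n_dec) sprintf("PRT%03d", seq_len(n_dec)),
             if (pp$n_background) sprintf("BG%02d", seq_len(pp$n_background)))
    is_int <- grepl("^INT", ids)
    is_bg <- grepl("^BG", ids)
    base <- rpois(length(ids), pp$mean_peptides) + 1
    base[is_bg] <- base[is_bg] * 5
    bait <- list(); control <- list()
    for (r in seq_len(pp$n_replicates)) {
      ctrl_counts <- rpois(length(ids), base)
      bait_counts <- rpois(length(ids), base)
      if (r == 1 && any(is_int)) {
        # guarantee >= 3x the fold-2 threshold against the realized control
        need <- ceiling(3 * (ctrl_counts[is_int] + 0.5) *
                          sum(bait_counts) / sum(ctrl_counts))
        bait_counts[is_int] <- pmax(rpois(sum(is_int), 4 * base[is_int]),
                                    need, 2)
      }
      ctrl_total <- sum(ctrl_counts)
      bait_total <- sum(bait_counts)
      # clamp non-planted proteins below 1.5x the fold-2 call threshold
      allowed <- floor(1.5 * (ctrl_counts / ctrl_total + 0.5 / ctrl_total) * bait_total)
      clamp <- !(is_int & r == 1)
      bait_counts[clamp] <- pmin(bait_counts[clamp], allowed[clamp])
      keep_b <- bait_counts > 0
      keep_c <- ctrl_counts > 0
      bait[[r]] <- peptide_table(
        data.frame(protein_id = ids[keep_b], unique_peptides = bait_counts[keep_b],
                   stringsAsFactors = FALSE), "bait", sprintf("rep%d", r))
      control[[r]] <- peptide_table(
        data.frame(protein_id = ids[keep_c], unique_peptides = ctrl_counts[keep_c],
                   stringsAsFactors = FALSE), "control", sprintf("rep%d", r))
    }
    list(bait = bait, control = control, background = ids[is_bg],
         truth = ids[is_int])
  })
}

#' Simulate a ChIP/input pair with planted enriched and depleted regions
#'
#' On dedicated small chromosomes, both libraries have a uniform rate of
#' `window_mean` fragments per `region_bp` window; planted enriched
#' regions multiply the ChIP rate by `fold`, planted depleted regions
#' divide it. Regions are `region_bp` wide and aligned to the window
#' grid, well separated from each other.
#'
#' @param cfg a [sim_config()].
#' @return list with `chip`, `input` ([fragment_set()]s),
#'   `chrom_sizes`, and `truth` (`enriched` / `depleted` interval
#'   data.frames).
#' @export
simulate_uhrf1 <- function(cfg) {
  withr::with_seed(cfg$seed + .STREAM[["uhrf1"]], {
    u <- cfg$uhrf1
    sizes <- u$chromosomes
    win <- .tile_windows(sizes, u$region_bp, u$region_bp)
    pick <- function(ch, k) {
      idx <- which(win$chrom == ch & win$end - win$start == u$region_bp)
      cand <- idx[seq(3, length(idx) - 3, by = 5)]
      sort(sample(cand, k))
    }
    enr <- pick(names(sizes)[1], u$n_enriched)
    dep <- pick(names(sizes)[2], u$n_depleted)
    rate <- rep(u$window_mean, nrow(win))
    chip_rate <- rate
    chip_rate[enr] <- chip_rate[enr] * u$fold
    chip_rate[dep] <- chip_rate[dep] / u$fold
    # libraries are sequenced to matched depth: rescale so the planted
    # fold is expressed in depth-normalized (CPM) units
    chip_rate <- chip_rate * sum(rate) / sum(chip_rate)
    make_lib <- function(rates, id) {
      counts <- rpois(length(rates), rates)
      idx <- rep(seq_along(counts), counts)
      mid <- win$start[idx] + floor(runif(length(idx)) * (win$end[idx] - win$start[idx]))
      .frags_from_mids(win$chrom[idx], mid, sizes, u$fragment_bp, id)
    }
    list(chip = make_lib(chip_rate, "Uhrf1_chip"),
         input = make_lib(rate, "Uhrf1_input"),
         chrom_sizes = sizes,
         truth = list(enriched = win[enr, c("chrom", "start", "end")],
                      depleted = win[dep, c("chrom", "start", "end")]))
  })
}

#' Null-calibrated promoter window simulation
#'
#' Draws `n` windows with input ~ Poisson(`input_mean`) and the ChIP
#' count at exactly the input-implied rate the Poisson test will use
#' (`lambda = (input_cpm + pc) * chip_libsize / 1e6`), i.e. the global
#' null. Returns the raw and BH-adjusted p-values and presence calls, so
#' the test's type-I behaviour can be measured directly.
#'
#' @param n number of windows (default 20000).
#' @param input_mean expected input fragments per window (default 50).
#' @param chip_libsize,input_libsize library sizes (default 1e6 each).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param seed RNG seed.
#' @return data.frame with `chip_count`, `input_count`, `p_value`,
#'   `q_value`, `present`.
#' @export
simulate_null_windows <- function(n = 20000, input_mean = 50,
                                  chip_libsize = 1e6, input_libsize = 1e6,
                                  pseudocount = 0.5, seed = 1) {
  withr::with_seed(seed, {
    input <- rpois(n, input_mean)
    lam <- (cpm_normalize(input, input_libsize) + pseudocount) * chip_libsize / 1e6
    chip <- rpois(n, lam)
    tw <- test_window(chip, input, chip_libsize, input_libsize, pseudocount)
    q <- bh_adjust(tw$p_enrich)
    data.frame(chip_count = chip, input_count = input,
               p_value = tw$p_enrich, q_value = q,
               present = tw$log2_ratio > 1 & q < 0.05)
  })
}

#' Run every generator from one configuration
#'
#' @param cfg a [sim_config()].
#' @return list with `config`, `annotation`, `states`, `chip`, `tf`,
#'   `atac`, `expression`, `peptides`, `uhrf1`.
#' @export
simulate_all <- function(cfg = sim_config()) {
  annotation <- simulate_annotation(cfg)
  states <- simulate_states(cfg, annotation)
  list(config = cfg,
       annotation = annotation,
       states = states,
       chip = simulate_chip(cfg, annotation, states),
       tf = simulate_tf_peaks(cfg),
       atac = simulate_atac(cfg),
       expression = simulate_expression(cfg),
       peptides = simulate_peptides(cfg),
       uhrf1 = simulate_uhrf1(cfg))
}
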