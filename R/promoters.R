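#' Mark-specific promoter window half-widths
#'
#' H3K4me3 is a sharp TSS-proximal mark and is quantified within +/-2 kb
#' of the TSS; H3K27me3 forms broader Polycomb domains and is quantified
#' within +/-5 kb.
#'
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @return half-width in bp.
#' @export
mark_halfwidth <- function(mark) {
  switch(match.arg(mark, c("H3K4me3", "H3K27me3")),
         H3K4me3 = 2000, H3K27me3 = 5000)
}

#' Quantify a histone mark over promoter windows
#'
#' Per gene, ChIP and input fragments are counted (by midpoint) in the
#' symmetric mark-specific TSS window, tested with the same Poisson
#' machinery as window calling, and BH-corrected across all promoters of
#' the mark. A mark is called present when `log2(ChIP/input) > 1` and
#' `q < alpha`.
#'
#' @param chip,input [fragment_set()]s for the mark and its input.
#' @param tss TSS annotation table; must be non-empty.
#' @param mark `"H3K4me3"` or `"H3K27me3"` (sets the half-width).
#' @param halfwidth override the mark-specific half-width (bp).
#' @param fold fold gate for presence (default 2).
#' @param alpha FDR threshold for presence (default 0.05).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame with one row per gene: window coordinates, raw
#'   counts, CPM values, `log2_ratio`, `p_value`, `q_value`, `present`.
#' @export
quantify_promoters <- function(chip, input, tss, mark = c("H3K4me3", "H3K27me3"),
                               halfwidth = NULL, fold = 2, alpha = 0.05,
                               pseudocount = 0.5) {
  mark <- match.arg(mark)
  tss <- validate_tss(tss)
  if (!nrow(tss)) .fail("empty TSS table")
  hw <- if (is.null(halfwidth)) mark_halfwidth(mark) else halfwidth
  win <- data.frame(chrom = tss$chrom,
                    start = pmax(0, tss$tss - hw),
                    end = tss$tss + hw,
                    stringsAsFactors = FALSE)
  chip_count <- count_fragments_in(chip, win)
  input_count <- count_fragments_in(input, win)
  tw <- test_window(chip_count, input_count, .lib_size(chip), .lib_size(input),
                    pseudocount = pseudocount)
  q <- bh_adjust(tw$p_enrich)
  data.frame(
    gene_id = tss$gene_id, mark = mark,
    chrom = win$chrom, start = win$start, end = win$end,
    chip_count = chip_count, input_count = input_count,
    chip_cpm = tw$chip_cpm, input_cpm = tw$input_cpm,
    log2_ratio = tw$log2_ratio,
    p_value = tw$p_enrich, q_value = q,
    present = tw$log2_ratio > log2(fold) & q < alpha,
    stringsAsFactors = FALSE
  )
}

#' Four-state promoter classification
#'
#' The state is the unique function of the two presence flags:
#' H3K4me3 only -> `active`; both -> `bivalent`; H3K27me3 only ->
#' `repressive`; neither -> `no_mark`.
#'
#' @param k4_present,k27_present logical vectors (recycled).
#' @return factor with levels `active`, `bivalent`, `repressive`,
#'   `no_mark`.
#' @export
classify_promoter <- function(k4_present, k27_present) {
  n <- max(length(k4_present), length(k27_present))
  k4 <- rep_len(as.logical(k4_present), n)
  k27 <- rep_len(as.logical(k27_present), n)
  if (any(is.na(k4)) || any(is.na(k27))) .fail("presence flags must be TRUE/FALSE")
  state <- ifelse(k4, ifelse(k27, "bivalent", "active"),
                  ifelse(k27, "repressive", "no_mark"))
  factor(state, levels = promoter_state_levels())
}

#' Promoter state levels, in display order
#' @return character vector `c("active","bivalent","repressive","no_mark")`.
#' @export
promoter_state_levels <- function() c("active", "bivalent", "repressive", "no_mark")

#' Combine per-mark promoter quantifications into state calls
#'
#' @param k4,k27 outputs of [quantify_promoters()] for H3K4me3 and
#'   H3K27me3 on the same gene universe.
#' @return data.frame with `gene_id`, per-mark `log2_ratio`/`q_value`/
#'   presence, and the four-level `state`.
#' @export
promoter_states <- function(k4, k27) {
  if (!setequal(k4$gene_id, k27$gene_id))
    .fail("mark tables cover different gene universes")
  k27 <- k27[match(k4$gene_id, k27$gene_id), ]
  data.frame(
    gene_id = k4$gene_id,
    k4_log2 = k4$log2_ratio, k4_q = k4$q_value, k4_present = k4$present,
    k27_log2 = k27$log2_ratio, k27_q = k27$q_value, k27_present = k27$present,
    state = classify_promoter(k4$present, k27$present),
    stringsAsFactors = FALSE
  )
}

# internal: accept a state data.frame or a named factor/character vector
.state_vec <- function(x) {
  if (is.data.frame(x)) {
    s <- x$state
    names(s) <- x$gene_id
  } else s <- x
  if (is.null(names(s))) .fail("states must be named by gene_id")
  setNames(factor(as.character(s), levels = promoter_state_levels()), names(s))
}

#' WT to KO promoter-state transition table
#'
#' Counts genes by (WT state, KO state) over the shared gene universe;
#' derives row percentages and the per-state retention rate (diagonal /
#' row sum). Empty WT classes yield `NA` retention, never 0.
#'
#' @param states_wt,states_ko state tables from [promoter_states()] (or
#'   named state vectors) on identical gene universes.
#' @return object of class `TransitionTable`: list with `counts` (4x4
#'   integer matrix), `row_pct`, `retention`, `n_genes`.
#' @export
transition_table <- function(states_wt, states_ko) {
  wt <- .state_vec(states_wt)
  ko <- .state_vec(states_ko)
  only_wt <- setdiff(names(wt), names(ko))
  only_ko <- setdiff(names(ko), names(wt))
  if (length(only_wt) || length(only_ko))
    .fail("gene universes differ; offenders: %s",
          paste(head(c(only_wt, only_ko), 10), collapse = ","))
  ko <- ko[match(names(wt), names(ko))]
  counts <- table(WT = wt, KO = ko)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(WT = promoter_state_levels(),
                                   KO = promoter_state_levels()))
  rs <- rowSums(counts)
  row_pct <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  retention <- diag(counts) / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, row_pct = row_pct,
                 retention = retention, n_genes = length(wt)),
            class = "TransitionTable")
}

#' @export
print.TransitionTable <- function(x, ...) {
  cat(sprintf("<TransitionTable> %d genes; WT -> KO row %%:\n", x$n_genes))
  print(round(x$row_pct, 2))
  cat("retention:", paste(sprintf("%s=%.3f", names(x$retention), x$retention),
                          collapse = " "), "\n")
  invisible(x)
}

#' Mean promoter signal by state class, with pairwise tests
#'
#' For each gene, the mean track value over bins overlapping
#' `TSS +/- halfwidth`; class means are compared pairwise with Welch
#' two-sided t-tests. Pairs where either class has fewer than 2 members,
#' or where both classes have zero variance, are skipped with a warning
#' (`p = NA`).
#'
#' @param track a CPM-normalized [make_binned_track()] result.
#' @param states state table from [promoter_states()].
#' @param tss TSS annotation table covering the state genes.
#' @param halfwidth window half-width in bp (default 2000).
#' @return list with `gene_signal` (per-gene values), `class_means`,
#'   and `tests` (data.frame class_a, class_b, p_value).
#' @export
signal_by_class <- function(track, states, tss, halfwidth = 2000) {
  tss <- validate_tss(tss)
  tss <- tss[match(states$gene_id, tss$gene_id), ]
  if (any(is.na(tss$gene_id))) .fail("TSS table missing genes from the state table")
  bw <- track$bin_width
  signal <- vapply(seq_len(nrow(tss)), function(i) {
    v <- track$values[[tss$chrom[i]]]
    if (is.null(v)) return(NA_real_)
    lo <- max(0, tss$tss[i] - halfwidth)
    hi <- tss$tss[i] + halfwidth
    bins <- (floor(lo / bw) + 1):min(ceiling(hi / bw), length(v))
    mean(v[bins])
  }, numeric(1))
  st <- .state_vec(states)
  gene_signal <- data.frame(gene_id = states$gene_id, state = st, signal = signal,
                            stringsAsFactors = FALSE)
  class_means <- tapply(signal, st, mean)
  pairs <- utils::combn(promoter_state_levels(), 2)
  tests <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                      p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    xa <- signal[st == pairs[1, i]]
    xb <- signal[st == pairs[2, i]]
    if (length(xa) < 2 || length(xb) < 2) {
      warning(sprintf("class pair %s/%s skipped: fewer than 2 members",
                      pairs[1, i], pairs[2, i]))
      next
    }
    if (var(xa) == 0 && var(xb) == 0) {
      warning(sprintf("class pair %s/%s skipped: zero variance",
                      pairs[1, i], pairs[2, i]))
      next
    }
    tests$p_value[i] <- stats::t.test(xa, xb)$p.value
  }
  list(gene_signal = gene_signal, class_means = class_means, tests = tests)
}
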