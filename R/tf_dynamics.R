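#' A named peak set for one factor and condition
#'
#' @param peaks interval data.frame of peaks (may be empty).
#' @param factor factor name, e.g. `"Oct4"`.
#' @param condition condition label, e.g. `"WT"`.
#' @return object of class `PeakSet`.
#' @export
peak_set <- function(peaks, factor = "factor", condition = "condition") {
  validate_intervals(peaks)
  structure(list(factor = factor, condition = condition, peaks = peaks),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("<PeakSet> %s/%s: %d peak(s)\n", x$factor, x$condition, nrow(x$peaks)))
  invisible(x)
}

.peak_df <- function(x) if (inherits(x, "PeakSet")) x$peaks else { validate_intervals(x); x }

# internal: for each row of a, TRUE iff some row of b lies within gap <= tol
.within_gap <- function(a, b, tol) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b), maxgap = tol))
  out <- rep(FALSE, nrow(a))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Compare two peak sets with a distance tolerance
#'
#' A peak of `a` is shared iff some peak of `b` lies within `tol` bp
#' edge-to-edge (gap 0 for overlapping/touching peaks); classification
#' is done per set against the other, so each peak is classified exactly
#' once and a peak may match several partners.
#'
#' @param a,b [peak_set()]s or interval data.frames.
#' @param tol maximum gap in bp to count as overlapping (default 100).
#' @return list with `a_specific`, `b_specific`, `a_shared`,
#'   `b_shared` (interval data.frames) and `shared_pairs`
#'   (data.frame of row indices `a_idx`, `b_idx` within `tol`).
#' @export
compare_peak_sets <- function(a, b, tol = 100) {
  pa <- .peak_df(a); pb <- .peak_df(b)
  a_sh <- .within_gap(pa, pb, tol)
  b_sh <- .within_gap(pb, pa, tol)
  pairs <- if (nrow(pa) && nrow(pb)) {
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(.as_granges(pa), .as_granges(pb), maxgap = tol))
    data.frame(a_idx = S4Vectors::queryHits(h), b_idx = S4Vectors::subjectHits(h))
  } else data.frame(a_idx = integer(), b_idx = integer())
  list(a_specific = pa[!a_sh, , drop = FALSE],
       b_specific = pb[!b_sh, , drop = FALSE],
       a_shared = pa[a_sh, , drop = FALSE],
       b_shared = pb[b_sh, , drop = FALSE],
       shared_pairs = pairs)
}

#' Fate categories for WT-specific Oct4 peaks
#' @return character vector of the four fates.
#' @export
fate_levels <- function() c("loss", "Sox2_replacement", "Nanog_replacement",
                            "Sox2_Nanog_replacement")

#' Classify WT-specific Oct4 peaks as lost or replaced
#'
#' Each WT-specific Oct4 peak is matched (gap `<= tol`) against
#' KO-specific Sox2 and Nanog peaks: a match to Sox2 only is
#' `Sox2_replacement`, to Nanog only `Nanog_replacement`, to both
#' `Sox2_Nanog_replacement`, and to neither `loss`. If a TSS table is
#' supplied, each peak is assigned its nearest gene as target.
#'
#' @param oct4_wt_specific WT-specific Oct4 peaks (already
#'   condition-specific, e.g. from [compare_peak_sets()]).
#' @param sox2_ko_specific,nanog_ko_specific KO-specific peak sets.
#' @param tss optional TSS annotation table for target genes.
#' @param tol maximum gap in bp (default 100).
#' @return list with `calls` (peak coordinates, `fate`, `target_gene`)
#'   and `fractions` (named vector over the four fates, summing to 1).
#' @export
classify_oct4_fate <- function(oct4_wt_specific, sox2_ko_specific,
                               nanog_ko_specific, tss = NULL, tol = 100) {
  oct4 <- .peak_df(oct4_wt_specific)
  if (!nrow(oct4)) {
    warning("empty Oct4 WT-specific peak set")
    return(list(calls = data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), fate = character(),
                                   target_gene = character()),
                fractions = setNames(rep(NA_real_, 4), fate_levels())))
  }
  s_hit <- .within_gap(oct4, .peak_df(sox2_ko_specific), tol)
  n_hit <- .within_gap(oct4, .peak_df(nanog_ko_specific), tol)
  fate <- ifelse(s_hit & n_hit, "Sox2_Nanog_replacement",
                 ifelse(s_hit, "Sox2_replacement",
                        ifelse(n_hit, "Nanog_replacement", "loss")))
  fate <- factor(fate, levels = fate_levels())
  calls <- data.frame(oct4[, c("chrom", "start", "end")],
                      fate = fate,
                      target_gene = if (is.null(tss)) NA_character_
                                    else nearest_tss(oct4, tss),
                      stringsAsFactors = FALSE)
  fractions <- as.vector(table(fate)) / nrow(oct4)
  names(fractions) <- fate_levels()
  list(calls = calls, fractions = fractions)
}

#' Nearest TSS gene for peaks
#'
#' The target of a peak is the gene whose TSS minimizes the distance to
#' the peak midpoint; ties go to the lexicographically smallest gene id;
#' peaks on chromosomes without any TSS get the sentinel `NA`.
#'
#' @param peaks interval data.frame (or [peak_set()]).
#' @param tss TSS annotation table.
#' @return character vector of gene ids (NA where no TSS available).
#' @export
nearest_tss <- function(peaks, tss) {
  pk <- .peak_df(peaks)
  tss <- validate_tss(tss)
  mids <- .midpoints(pk)
  out <- rep(NA_character_, nrow(pk))
  for (ch in unique(pk$chrom)) {
    tt <- tss[tss$chrom == ch, ]
    if (!nrow(tt)) next
    idx <- which(pk$chrom == ch)
    for (i in idx) {
      d <- abs(tt$tss - mids[i])
      cand <- tt$gene_id[d == min(d)]
      out[i] <- sort(cand)[1]
    }
  }
  out
}

#' Keep sub-nucleosomal fragments
#'
#' Retains fragments strictly shorter than `max_bp` (`end - start <
#' max_bp`), the nucleosome-free ATAC fraction at the default
#' mono-nucleosome threshold of 150 bp; the library size is updated to
#' the retained count.
#'
#' @param fragments a [fragment_set()] or interval data.frame.
#' @param max_bp exclusive size threshold (default 150).
#' @return a `FragmentSet` of the retained fragments.
#' @export
filter_fragments_by_size <- function(fragments, max_bp = 150) {
  frag <- .frag_df(fragments)
  id <- if (inherits(fragments, "FragmentSet")) fragments$library_id else "library"
  keep <- (frag$end - frag$start) < max_bp
  fragment_set(frag[keep, , drop = FALSE], library_id = id)
}

#' Compare normalized signal within peaks between two libraries
#'
#' Per peak, CPM-normalized WT and KO fragment counts and
#' `log2((KO + pc)/(WT + pc))`; the summary is a two-sided paired t-test
#' of the per-peak log2 ratios against 0 (the two quantities are
#' measured on the same regions).
#'
#' @param wt,ko [fragment_set()]s for the two conditions.
#' @param peaks interval data.frame (or [peak_set()]) with >= 2 peaks.
#' @param pseudocount CPM pseudocount for the per-peak ratio (default 0.5).
#' @return list with `per_peak` (counts, CPM, `log2_ratio` per peak) and
#'   `summary` (`mean_log2_ratio`, `p_value`, `zero_variance`,
#'   `n_peaks`). With identical libraries the test is degenerate:
#'   `p_value = 1` with `zero_variance = TRUE`.
#' @export
signal_in_peaks_test <- function(wt, ko, peaks, pseudocount = 0.5) {
  pk <- .peak_df(peaks)
  if (nrow(pk) < 2) .fail("need >= 2 peaks")
  if (nrow(pk) == 2) warning("only 2 peaks: low-power comparison")
  wt_count <- count_fragments_in(wt, pk)
  ko_count <- count_fragments_in(ko, pk)
  wt_cpm <- cpm_normalize(wt_count, .lib_size(wt))
  ko_cpm <- cpm_normalize(ko_count, .lib_size(ko))
  lr <- log2((ko_cpm + pseudocount) / (wt_cpm + pseudocount))
  zero_var <- sd(lr) == 0
  p <- if (zero_var) 1 else stats::t.test(lr, mu = 0)$p.value
  list(per_peak = data.frame(pk[, c("chrom", "start", "end")],
                             wt_count = wt_count, ko_count = ko_count,
                             wt_cpm = wt_cpm, ko_cpm = ko_cpm,
                             log2_ratio = lr),
       summary = list(mean_log2_ratio = mean(lr), p_value = p,
                      zero_variance = zero_var, n_peaks = nrow(pk)))
}
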