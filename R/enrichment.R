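#' Upper-tail Poisson p-value
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, the enrichment p-value used for
#' all ChIP-versus-input tests in this package: the observed ChIP count
#' is compared against the rate implied by the depth-normalized input.
#' Returns 1 for `k = 0` (the whole support).
#'
#' @param k observed count(s); non-negative integer(s).
#' @param lam expected rate(s) under the null; must be `> 0` (apply a
#'   pseudocount upstream for zero-input windows).
#' @return numeric vector of upper-tail probabilities.
#' @export
poisson_upper_pvalue <- function(k, lam) {
  if (!.is_count(k)) .fail("k must be non-negative integer(s)")
  if (any(is.na(lam)) || any(lam <= 0)) .fail("lam must be > 0")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, `q_(i) = min_{j >= i} p_(j) * n / j`,
#' clipped at 1, returned in the original order. Implemented directly so
#' it can be verified against an independent step-up in the test suite.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) .fail("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Poisson ChIP-versus-input test for one window (vectorized)
#'
#' Both directions are tested symmetrically: enrichment compares the
#' ChIP count against the input-implied rate rescaled to ChIP depth,
#' `lambda = (input_cpm + pc) * chip_libsize / 1e6`; depletion compares
#' the input count against the ChIP-implied rate rescaled to input
#' depth. The fold change is `log2((chip_cpm + pc)/(input_cpm + pc))`.
#' q-values are not filled here; callers apply [bh_adjust()] jointly
#' across all windows of a run, per direction.
#'
#' @param chip_count,input_count raw fragment counts.
#' @param chip_libsize,input_libsize library sizes (> 0).
#' @param pseudocount CPM pseudocount added to both normalized values
#'   before the ratio and the rate (default 0.5).
#' @return data.frame with `chip_cpm`, `input_cpm`, `log2_ratio`,
#'   `p_enrich`, `p_deplete`.
#' @export
test_window <- function(chip_count, input_count, chip_libsize, input_libsize,
                        pseudocount = 0.5) {
  if (!.is_count(chip_count) || !.is_count(input_count)) .fail("counts must be non-negative integers")
  chip_cpm <- cpm_normalize(chip_count, chip_libsize)
  input_cpm <- cpm_normalize(input_count, input_libsize)
  lam_chip <- (input_cpm + pseudocount) * chip_libsize / 1e6
  lam_input <- (chip_cpm + pseudocount) * input_libsize / 1e6
  data.frame(
    chip_cpm = chip_cpm,
    input_cpm = input_cpm,
    log2_ratio = log2((chip_cpm + pseudocount) / (input_cpm + pseudocount)),
    p_enrich = poisson_upper_pvalue(chip_count, lam_chip),
    p_deplete = poisson_upper_pvalue(input_count, lam_input)
  )
}

# internal: tile chromosomes with windows of window_bp at step_bp
.tile_windows <- function(chrom_sizes, window_bp, step_bp) {
  pieces <- lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, max(0, chrom_sizes[[ch]] - 1), by = step_bp)
    ends <- pmin(starts + window_bp, chrom_sizes[[ch]])
    keep <- ends > starts
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# internal: merge overlapping/adjacent windows, score = -log10(min q)
.merge_called <- function(windows, q, label) {
  if (!nrow(windows)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  gr <- .as_granges(windows)
  red <- IRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 1L)
  out <- .from_granges(red)
  revmap <- S4Vectors::mcols(red)$revmap
  out$name <- sprintf("%s_%d", label, seq_len(nrow(out)))
  out$score <- vapply(revmap, function(ii) -log10(max(min(q[ii]), 1e-300)), numeric(1))
  out
}

#' Call enriched and depleted regions by windowed Poisson testing
#'
#' Windows of `window_bp` tile each chromosome at `step_bp` (default:
#' non-overlapping tiling; smaller steps give a sliding scan at the
#' cost of smeared region edges). Every window is tested with
#' [test_window()]; BH correction is applied jointly across all windows
#' of the run, separately per direction; windows passing both the fold
#' gate and `q < alpha` are merged by interval union.
#'
#' @param chip,input [fragment_set()]s (or interval data.frames).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window_bp window size in bp (default 10000).
#' @param step_bp step between window starts (default `window_bp`).
#' @param fold minimum fold difference (default 2, i.e. |log2| > 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return list of class `RegionCallSet` with elements `enriched`,
#'   `depleted` (merged interval data.frames with `name` and
#'   `score = -log10(min q)`), `windows` (the full per-window test
#'   table) and `params`.
#' @export
call_differential_windows <- function(chip, input, chrom_sizes,
                                      window_bp = 10000, step_bp = window_bp,
                                      fold = 2, alpha = 0.05,
                                      pseudocount = 0.5) {
  if (window_bp <= 0 || step_bp <= 0) .fail("window_bp and step_bp must be > 0")
  if (.lib_size(chip) == 0 || .lib_size(input) == 0) .fail("empty library")
  win <- .tile_windows(chrom_sizes, window_bp, step_bp)
  chip_count <- count_fragments_in(chip, win)
  input_count <- count_fragments_in(input, win)
  tw <- test_window(chip_count, input_count, .lib_size(chip), .lib_size(input),
                    pseudocount = pseudocount)
  win <- cbind(win, chip_count = chip_count, input_count = input_count, tw)
  win$q_enrich <- bh_adjust(win$p_enrich)
  win$q_deplete <- bh_adjust(win$p_deplete)
  lf <- log2(fold)
  enr <- win$log2_ratio > lf & win$q_enrich < alpha
  dep <- win$log2_ratio < -lf & win$q_deplete < alpha
  win$call <- ifelse(enr, "enriched", ifelse(dep, "depleted", "none"))
  structure(
    list(enriched = .merge_called(win[enr, c("chrom", "start", "end")], win$q_enrich[enr], "enriched"),
         depleted = .merge_called(win[dep, c("chrom", "start", "end")], win$q_deplete[dep], "depleted"),
         windows = win,
         params = list(window_bp = window_bp, step_bp = step_bp, fold = fold,
                       alpha = alpha, pseudocount = pseudocount)),
    class = "RegionCallSet")
}

#' @export
print.RegionCallSet <- function(x, ...) {
  cat(sprintf("<RegionCallSet> %d enriched, %d depleted region(s) from %d windows (window %d bp, step %d bp, fold %g, alpha %g)\n",
              nrow(x$enriched), nrow(x$depleted), nrow(x$windows),
              as.integer(x$params$window_bp), as.integer(x$params$step_bp),
              x$params$fold, x$params$alpha))
  invisible(x)
}

#' Annotate regions as promoter / gene body / intergenic
#'
#' Precedence: a region overlapping any `TSS +/- promoter_halfwidth`
#' window is `promoter`; otherwise one overlapping a gene body is
#' `gene_body`; otherwise `intergenic`.
#'
#' @param regions interval data.frame of regions to label.
#' @param genes interval data.frame of gene bodies.
#' @param tss TSS annotation table (see [read_tss_table()]).
#' @param promoter_halfwidth promoter window half-width (default 2000).
#' @return list with `regions` (input plus a `category` column) and
#'   `tally` (data.frame of per-category counts and fractions summing
#'   to 1).
#' @export
annotate_regions <- function(regions, genes, tss, promoter_halfwidth = 2000) {
  validate_intervals(regions)
  cats <- c("promoter", "gene_body", "intergenic")
  category <- rep("intergenic", nrow(regions))
  if (nrow(regions)) {
    rg <- .as_granges(regions)
    if (nrow(tss)) {
      prom <- data.frame(chrom = tss$chrom,
                         start = pmax(0, tss$tss - promoter_halfwidth),
                         end = tss$tss + promoter_halfwidth)
      hit_prom <- suppressWarnings(
        GenomicRanges::countOverlaps(rg, .as_granges(prom))) > 0
    } else hit_prom <- logical(nrow(regions))
    if (NROW(genes)) {
      hit_gene <- suppressWarnings(
        GenomicRanges::countOverlaps(rg, .as_granges(genes))) > 0
    } else hit_gene <- logical(nrow(regions))
    category[hit_gene] <- "gene_body"
    category[hit_prom] <- "promoter"
  }
  regions$category <- factor(category, levels = cats)
  n <- as.vector(table(regions$category))
  tally <- data.frame(category = cats, n = n,
                      fraction = if (sum(n)) n / sum(n) else rep(NA_real_, 3))
  list(regions = regions, tally = tally)
}
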