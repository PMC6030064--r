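#' Construct an expression matrix with sample metadata
#'
#' @param values numeric genes x samples matrix of RPKM (>= 0), with
#'   row names (gene ids) and column names (sample labels).
#' @param samples data.frame with columns `sample`, `condition`
#'   (`"WT"`/`"KO"`), `timepoint`; `sample` must match the matrix
#'   columns.
#' @return object of class `ExpressionMatrix`: list with `values`,
#'   `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    .fail("values must be a matrix with gene row names and sample column names")
  if (any(values < 0)) .fail("negative expression values")
  if (anyDuplicated(colnames(values))) .fail("duplicate sample labels")
  need <- c("sample", "condition", "timepoint")
  if (!all(need %in% names(samples))) .fail("sample sheet needs columns %s",
                                            paste(need, collapse = ", "))
  if (!setequal(samples$sample, colnames(values)))
    .fail("sample sheet does not match matrix columns")
  samples <- samples[match(colnames(values), samples$sample), ]
  structure(list(values = values, samples = samples), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = "/")))
  invisible(x)
}

#' Select genes with dynamic expression
#'
#' Keeps a gene iff, for some sample, the pseudocounted RPKM ratio to
#' the reference sample exceeds `fold` in either direction (strictly).
#'
#' @param em an [expression_matrix()].
#' @param reference_sample sample label used as the ratio denominator
#'   (typically WT at the first timepoint).
#' @param fold fold-change threshold (default 1.5).
#' @param pseudocount added to numerator and denominator (default 1).
#' @return character vector of retained gene ids.
#' @export
filter_dynamic_genes <- function(em, reference_sample, fold = 1.5, pseudocount = 1) {
  v <- em$values
  if (!reference_sample %in% colnames(v)) .fail("reference sample %s not found", reference_sample)
  ratio <- (v + pseudocount) / (v[, reference_sample] + pseudocount)
  keep <- apply(ratio, 1, function(r) any(r > fold | r < 1 / fold))
  rownames(v)[keep]
}

#' Cluster genes into transcriptional modules
#'
#' Euclidean distances on `log2(RPKM + pseudocount)` profiles,
#' agglomerative Ward.D2 linkage, flat modules by cutting the dendrogram
#' at `height`. Module ids are renumbered in order of first appearance
#' along the input gene order.
#'
#' @param em an [expression_matrix()].
#' @param genes gene subset to cluster (default: all rows), e.g. from
#'   [filter_dynamic_genes()].
#' @param height dendrogram cut height (default 20; its meaning scales
#'   with gene count and profile magnitude, so expose it).
#' @param pseudocount added before log2 (default 1).
#' @return object of class `ModuleAssignment`: list with `modules`
#'   (named integer vector gene -> module), `height`, `hclust`.
#' @export
cluster_modules <- function(em, genes = NULL, height = 20, pseudocount = 1) {
  v <- em$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) .fail("unknown genes: %s", paste(head(missing, 5), collapse = ","))
    v <- v[genes, , drop = FALSE]
  }
  if (nrow(v) < 2) .fail("need >= 2 genes to cluster")
  lv <- log2(v + pseudocount)
  hc <- hclust(dist(lv), method = "ward.D2")
  raw <- cutree(hc, h = min(height, max(hc$height)))
  modules <- as.integer(factor(raw, levels = unique(raw)))
  names(modules) <- rownames(v)
  structure(list(modules = modules, height = height, hclust = hc),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat(sprintf("<ModuleAssignment> %d genes in %d module(s) (cut height %g)\n",
              length(x$modules), length(unique(x$modules)), x$height))
  invisible(x)
}

#' Mean relative expression profile per module
#'
#' Per gene, relative expression is `(rpkm + pc)/(rpkm_ref + pc)`;
#' per module and sample the mean and SEM across member genes are
#' reported (SEM is `NA` for single-gene modules).
#'
#' @param assign a [cluster_modules()] result.
#' @param em an [expression_matrix()] covering the assigned genes.
#' @param reference_sample denominator sample label.
#' @param pseudocount default 1.
#' @return data.frame with `module`, `sample`, `condition`, `timepoint`,
#'   `mean_rel`, `sem`, `n_genes`.
#' @export
module_profiles <- function(assign, em, reference_sample, pseudocount = 1) {
  v <- em$values[names(assign$modules), , drop = FALSE]
  if (!reference_sample %in% colnames(v)) .fail("reference sample %s not found", reference_sample)
  rel <- (v + pseudocount) / (v[, reference_sample] + pseudocount)
  out <- do.call(rbind, lapply(sort(unique(assign$modules)), function(m) {
    rows <- rel[assign$modules == m, , drop = FALSE]
    n <- nrow(rows)
    data.frame(module = m, sample = colnames(rows),
               mean_rel = colMeans(rows),
               sem = if (n > 1) apply(rows, 2, sd) / sqrt(n) else NA_real_,
               n_genes = n, row.names = NULL, stringsAsFactors = FALSE)
  }))
  out <- merge(out, em$samples, by = "sample", sort = FALSE)
  out[order(out$module, out$timepoint, out$condition),
      c("module", "sample", "condition", "timepoint", "mean_rel", "sem", "n_genes")]
}

#' Flag modules with significant WT/KO expression differences
#'
#' Per module and timepoint present in both conditions: the ratio of
#' mean member expression (KO vs WT, pseudocounted) and a two-sided
#' paired t-test across member genes. A module/timepoint is flagged when
#' the ratio exceeds `fold` in either direction AND `p < alpha`.
#' Modules with fewer than 2 genes get `NA` flags.
#'
#' @param assign a [cluster_modules()] result.
#' @param em an [expression_matrix()] with both conditions.
#' @param fold ratio gate (default 1.25).
#' @param alpha t-test significance level (default 0.05).
#' @param pseudocount default 1.
#' @return data.frame with `module`, `timepoint`, `ratio`, `p_value`,
#'   `flag`, `n_genes`.
#' @export
module_significance <- function(assign, em, fold = 1.25, alpha = 0.05,
                                pseudocount = 1) {
  v <- em$values[names(assign$modules), , drop = FALSE]
  ss <- em$samples
  tps <- sort(unique(ss$timepoint))
  out <- list()
  for (tp in tps) {
    wt_s <- ss$sample[ss$condition == "WT" & ss$timepoint == tp]
    ko_s <- ss$sample[ss$condition == "KO" & ss$timepoint == tp]
    if (!length(wt_s) || !length(ko_s)) next
    wt_val <- rowMeans(v[, wt_s, drop = FALSE])
    ko_val <- rowMeans(v[, ko_s, drop = FALSE])
    for (m in sort(unique(assign$modules))) {
      sel <- assign$modules == m
      n <- sum(sel)
      if (n < 2) {
        out[[length(out) + 1]] <- data.frame(module = m, timepoint = tp,
                                             ratio = NA_real_, p_value = NA_real_,
                                             flag = NA, n_genes = n)
        next
      }
      ratio <- (mean(ko_val[sel]) + pseudocount) / (mean(wt_val[sel]) + pseudocount)
      d <- ko_val[sel] - wt_val[sel]
      p <- if (sd(d) == 0) { if (mean(d) == 0) 1 else NA_real_ }
           else stats::t.test(ko_val[sel], wt_val[sel], paired = TRUE)$p.value
      gate <- ratio > fold | ratio < 1 / fold
      flag <- if (!gate) FALSE else if (is.na(p)) NA else (p < alpha)
      out[[length(out) + 1]] <- data.frame(module = m, timepoint = tp,
                                           ratio = ratio, p_value = p,
                                           flag = flag, n_genes = n)
    }
  }
  do.call(rbind, out)
}
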