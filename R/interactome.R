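#' Construct a peptide-count table for one pull-down replicate
#'
#' The normalization total (unique peptides over all sequenced proteins)
#' is frozen at construction, i.e. computed before any protein is
#' removed, so later filtering does not change fractions.
#'
#' @param counts data.frame with columns `protein_id`,
#'   `unique_peptides` (non-negative integers; ids unique).
#' @param channel `"bait"` or `"control"`.
#' @param replicate replicate label.
#' @return object of class `PeptideTable`: list with `counts`,
#'   `channel`, `replicate`, `total`.
#' @export
peptide_table <- function(counts, channel = c("bait", "control"), replicate = "rep1") {
  channel <- match.arg(channel)
  need <- c("protein_id", "unique_peptides")
  if (!all(need %in% names(counts))) .fail("need columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(counts$protein_id)) .fail("duplicate protein_id")
  if (!.is_count(counts$unique_peptides)) .fail("unique_peptides must be non-negative integers")
  total <- sum(counts$unique_peptides)
  if (total <= 0) .fail("total unique peptides must be > 0")
  structure(list(counts = counts[, need], channel = channel,
                 replicate = replicate, total = total),
            class = "PeptideTable")
}

#' @export
print.PeptideTable <- function(x, ...) {
  cat(sprintf("<PeptideTable> %s %s: %d proteins, %d total unique peptides\n",
              x$channel, x$replicate, nrow(x$counts), x$total))
  invisible(x)
}

.pep_tab <- function(x, channel = "bait", replicate = "rep") {
  if (inherits(x, "PeptideTable")) x else peptide_table(x, channel, replicate)
}

#' Read a peptide-count table from a tab-delimited file
#'
#' @param path file with header columns `protein_id`, `unique_peptides`.
#' @param channel,replicate passed to [peptide_table()].
#' @return a `PeptideTable`.
#' @export
read_peptide_table <- function(path, channel = c("bait", "control"), replicate = "rep1") {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  peptide_table(dt, channel = match.arg(channel), replicate = replicate)
}

#' Remove low-evidence and background proteins
#'
#' Drops proteins with fewer than `min_peptides` unique peptides in this
#' table and any protein on the common-background list. The
#' normalization total is NOT recomputed (it was frozen at table
#' construction, before the drop).
#'
#' @param t a [peptide_table()] (or bare counts data.frame).
#' @param background character vector of background protein ids.
#' @param min_peptides minimum unique peptides (default 2).
#' @return a `PeptideTable` with filtered rows and the original total.
#' @export
prefilter_proteins <- function(t, background = character(), min_peptides = 2) {
  t <- .pep_tab(t)
  keep <- t$counts$unique_peptides >= min_peptides &
    !(t$counts$protein_id %in% background)
  t$counts <- t$counts[keep, , drop = FALSE]
  t
}

#' Call candidate interactors from bait and control replicates
#'
#' Per replicate pair, each protein's normalized fraction
#' (`count / total`, totals frozen before filtering) is compared:
#' `ratio_r = bait_fraction / (control_fraction + pseudo)`. A protein is
#' a candidate iff it survives [prefilter_proteins()] in some bait
#' replicate `r` AND `ratio_r >= fold` in that replicate. With unequal
#' replicate counts every bait replicate is compared against the pooled
#' control fractions.
#'
#' @param bait_reps list of bait [peptide_table()]s.
#' @param control_reps list of control [peptide_table()]s.
#' @param background character vector of background protein ids.
#' @param min_peptides minimum unique peptides per bait replicate
#'   (default 2).
#' @param fold fold threshold on normalized fractions (default 2).
#' @param pseudo_fraction added to the control fraction; default
#'   `0.5 / control_total` (half a peptide), so proteins absent from the
#'   control keep a finite ratio.
#' @return list with `calls` (per protein: `max_ratio`, `n_pass`,
#'   `candidate`) and `per_replicate` (long table of fractions and
#'   ratios).
#' @export
call_interactors <- function(bait_reps, control_reps, background = character(),
                             min_peptides = 2, fold = 2, pseudo_fraction = NULL) {
  if (inherits(bait_reps, "PeptideTable")) bait_reps <- list(bait_reps)
  if (inherits(control_reps, "PeptideTable")) control_reps <- list(control_reps)
  if (!length(bait_reps) || !length(control_reps)) .fail("need >= 1 bait and control replicate")
  bait_reps <- lapply(bait_reps, .pep_tab)
  control_reps <- lapply(control_reps, .pep_tab)
  paired <- length(bait_reps) == length(control_reps)
  pool_counts <- NULL
  if (!paired) {
    ids <- unique(unlist(lapply(control_reps, function(t) t$counts$protein_id)))
    pool_counts <- sapply(ids, function(id) {
      sum(vapply(control_reps, function(t) {
        i <- match(id, t$counts$protein_id)
        if (is.na(i)) 0 else t$counts$unique_peptides[i]
      }, numeric(1)))
    })
    pool_total <- sum(vapply(control_reps, `[[`, numeric(1), "total"))
  }
  proteins <- unique(unlist(lapply(bait_reps, function(t) t$counts$protein_id)))
  rep_rows <- list()
  for (r in seq_along(bait_reps)) {
    bt <- bait_reps[[r]]
    if (paired) {
      ct <- control_reps[[r]]
      ctrl_frac_of <- function(id) {
        i <- match(id, ct$counts$protein_id)
        if (is.na(i)) 0 else ct$counts$unique_peptides[i] / ct$total
      }
      ctrl_total <- ct$total
    } else {
      ctrl_frac_of <- function(id) {
        i <- match(id, names(pool_counts))
        if (is.na(i)) 0 else pool_counts[[i]] / pool_total
      }
      ctrl_total <- pool_total
    }
    pseudo <- if (is.null(pseudo_fraction)) 0.5 / ctrl_total else pseudo_fraction
    kept <- prefilter_proteins(bt, background, min_peptides)$counts$protein_id
    bi <- match(proteins, bt$counts$protein_id)
    bait_count <- ifelse(is.na(bi), 0, bt$counts$unique_peptides[bi])
    bait_frac <- bait_count / bt$total
    ctrl_frac <- vapply(proteins, ctrl_frac_of, numeric(1))
    ratio <- bait_frac / (ctrl_frac + pseudo)
    rep_rows[[r]] <- data.frame(
      protein_id = proteins, replicate = r,
      bait_count = bait_count, bait_fraction = bait_frac,
      control_fraction = ctrl_frac, ratio = ratio,
      pass = proteins %in% kept & ratio >= fold,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rep_rows)
  calls <- do.call(rbind, lapply(split(long, long$protein_id), function(d) {
    data.frame(protein_id = d$protein_id[1],
               max_ratio = max(d$ratio),
               n_pass = sum(d$pass),
               candidate = any(d$pass),
               stringsAsFactors = FALSE)
  }))
  calls <- calls[match(proteins, calls$protein_id), ]
  rownames(calls) <- NULL
  list(calls = calls, per_replicate = long)
}
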