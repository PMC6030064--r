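#' Construct a genomic interval table
#'
#' Coordinates are 0-based half-open (BED convention) throughout the
#' package: a fragment occupying the first 100 bases of a chromosome is
#' `start = 0, end = 100`. Strand is carried but ignored by all counting
#' operations (promoter windows are symmetric around the TSS).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (unspecified); recycled.
#' @param name optional labels; recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom)),
    name = rep_len(as.character(name), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the invariants every interval in the package must satisfy:
#' non-empty chromosome names and `0 <= start < end`.
#'
#' @param x a data.frame with at least `chrom`, `start`, `end` columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    .fail("intervals must be a data.frame with chrom/start/end columns")
  if (nrow(x)) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom))) .fail("empty chromosome name")
    if (any(is.na(x$start) | is.na(x$end))) .fail("NA coordinates")
    if (any(x$start < 0)) .fail("negative start coordinate")
    if (any(x$start >= x$end)) .fail("start >= end in interval table")
  }
  invisible(x)
}

# internal: interval df -> GRanges (1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# internal: GRanges -> interval df (back to 0-based half-open)
.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read a BED3/BED6 file
#'
#' BED coordinates are already 0-based half-open and are used verbatim.
#' Columns beyond the sixth are ignored. Malformed coordinate fields or
#' `start >= end` raise an error naming the offending line.
#'
#' @param path path to a tab-separated BED file without header.
#' @return a data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .fail("no such file: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 3) .fail("BED file needs >= 3 tab-separated fields: %s", path)
  dt <- dt[, seq_len(min(ncol(dt), 6L)), drop = FALSE]
  names(dt) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(dt))]
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) .fail("non-integer %s coordinate at line %d", col, bad[1])
    dt[[col]] <- v
  }
  bad <- which(dt$start >= dt$end)
  if (length(bad)) .fail("start >= end at line %d", bad[1])
  if (any(dt$start < 0)) .fail("negative start at line %d", which(dt$start < 0)[1])
  if ("score" %in% names(dt)) dt$score <- suppressWarnings(as.numeric(dt$score))
  dt
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, if present, `name`, `score`,
#' `strand` (in that order, truncated at the last present column), so
#' that `read_bed()` output round-trips byte-identically.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- cols[seq_len(max(which(cols %in% names(x))))]
  out <- x[, intersect(keep, names(x)), drop = FALSE]
  # BED columns are positional: fill gaps with conventional defaults
  if (!"name" %in% names(out) && length(keep) > 3) out$name <- "."
  if (!"score" %in% names(out) && length(keep) > 4) out$score <- 0
  out <- out[, keep, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path text file with `chrom<TAB>length` lines.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 2) .fail("chrom sizes file needs 2 columns")
  sizes <- as.numeric(dt[[2]])
  names(sizes) <- as.character(dt[[1]])
  if (any(is.na(sizes) | sizes <= 0)) .fail("invalid chromosome length")
  sizes
}

#' Write a chromosome-sizes file
#' @param sizes named numeric vector of chromosome lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  data.table::fwrite(
    data.frame(chrom = names(sizes),
               size = format(sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `strand`,
#' `tss` (0-based position). Gene ids must be unique.
#'
#' @param path input path.
#' @return data.frame with those four columns.
#' @export
read_tss_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  validate_tss(dt)
}

#' Validate a TSS annotation table
#' @param x data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @return `x`, invisibly reordered columns, if valid.
#' @export
validate_tss <- function(x) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(x))) .fail("TSS table needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(x$gene_id)) .fail("duplicate gene_id in TSS table")
  if (any(x$tss < 0)) .fail("negative TSS position")
  x[, union(need, names(x))]
}

#' Write a TSS annotation table
#' @param x TSS table as from [read_tss_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(x, path) {
  validate_tss(x)
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' A sequencing library as a set of fragments
#'
#' Bundles an interval table of fragments with its library id; the
#' library size (total fragment count, the CPM denominator) is the
#' number of fragments.
#'
#' @param fragments interval data.frame (see [genomic_intervals()]).
#' @param library_id character label.
#' @return an object of class `FragmentSet`: a list with elements
#'   `library_id`, `fragments`, `library_size`.
#' @export
fragment_set <- function(fragments, library_id = "library") {
  validate_intervals(fragments)
  structure(
    list(library_id = as.character(library_id),
         fragments = fragments,
         library_size = nrow(fragments)),
    class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("<FragmentSet> %s: %d fragments on %d chromosome(s)\n",
              x$library_id, x$library_size,
              length(unique(x$fragments$chrom))))
  invisible(x)
}

# internal: accept FragmentSet or bare interval df
.frag_df <- function(x) {
  if (inherits(x, "FragmentSet")) x$fragments else { validate_intervals(x); x }
}

# internal: library size of FragmentSet or df
.lib_size <- function(x) if (inherits(x, "FragmentSet")) x$library_size else nrow(.frag_df(x))

# internal: fragment midpoints, floor((start+end)/2)
.midpoints <- function(df) floor((df$start + df$end) / 2)

#' Count fragments in regions by midpoint
#'
#' A fragment is assigned to the single region containing its midpoint
#' `floor((start+end)/2)` under the half-open rule, so counts over a
#' partition of the genome conserve the library size.
#'
#' @param fragments a [fragment_set()] or interval data.frame.
#' @param regions interval data.frame of one or more query regions.
#' @return integer vector of counts, one per region row.
#' @export
count_fragments_in <- function(fragments, regions) {
  frag <- .frag_df(fragments)
  validate_intervals(regions)
  mids <- .midpoints(frag)
  out <- integer(nrow(regions))
  if (!nrow(frag) || !nrow(regions)) return(out)
  for (ch in unique(regions$chrom)) {
    m <- sort(mids[frag$chrom == ch])
    idx <- which(regions$chrom == ch)
    if (!length(m)) next
    # mids in [start, end)  =  #(m <= end-1) - #(m <= start-1)
    out[idx] <- findInterval(regions$end[idx] - 1, m) -
      findInterval(regions$start[idx] - 1, m)
  }
  out
}

#' Counts-per-million normalization
#'
#' @param count raw fragment count(s).
#' @param library_size total mapped fragments in the library (> 0).
#' @return `count / library_size * 1e6`.
#' @export
cpm_normalize <- function(count, library_size) {
  if (any(library_size <= 0)) .fail("library_size must be > 0")
  count / library_size * 1e6
}

#' Build a binned, depth-normalized coverage track
#'
#' Each fragment contributes 1 to the bin containing its midpoint; bins
#' tile each chromosome from 0 in `bin_width` steps. Values are
#' fragments per million (CPM) unless `normalize = FALSE`.
#'
#' @param fragments a [fragment_set()] or interval data.frame.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_width bin size in bp (> 0).
#' @param normalize divide bin counts by library size x 1e-6.
#' @return an object of class `BinnedTrack`: list with `bin_width`,
#'   `values` (named list of per-chromosome numeric vectors),
#'   `library_size`, `normalized`.
#' @export
make_binned_track <- function(fragments, chrom_sizes, bin_width, normalize = TRUE) {
  if (length(bin_width) != 1 || bin_width <= 0) .fail("bin_width must be a single value > 0")
  frag <- .frag_df(fragments)
  lib <- .lib_size(fragments)
  missing_chr <- setdiff(unique(frag$chrom), names(chrom_sizes))
  if (length(missing_chr))
    .fail("fragment chromosome(s) absent from chrom_sizes: %s",
          paste(missing_chr, collapse = ","))
  mids <- .midpoints(frag)
  values <- lapply(names(chrom_sizes), function(ch) {
    n_bins <- ceiling(chrom_sizes[[ch]] / bin_width)
    m <- mids[frag$chrom == ch]
    if (length(m) && any(m >= n_bins * bin_width | m < 0))
      .fail("fragment midpoint outside chromosome %s", ch)
    v <- tabulate(floor(m / bin_width) + 1L, nbins = n_bins)
    if (normalize && lib > 0) v / lib * 1e6 else as.numeric(v)
  })
  names(values) <- names(chrom_sizes)
  structure(
    list(bin_width = bin_width, values = values,
         library_size = lib, normalized = normalize),
    class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("<BinnedTrack> bin %d bp, %d chromosome(s), %d bins%s\n",
              as.integer(x$bin_width), length(x$values),
              sum(lengths(x$values)),
              if (x$normalized) ", CPM-normalized" else ", raw counts"))
  invisible(x)
}

#' Genome-wide Pearson correlation of two binned tracks
#'
#' Correlates the concatenated per-bin vectors of two tracks with
#' identical binning. Zero variance in either track is an error rather
#' than a silent 0.
#'
#' @param a,b `BinnedTrack` objects with identical `bin_width` and
#'   chromosome partitions.
#' @return Pearson correlation coefficient.
#' @export
track_pearson <- function(a, b) {
  if (!inherits(a, "BinnedTrack") || !inherits(b, "BinnedTrack"))
    .fail("inputs must be BinnedTrack objects")
  if (a$bin_width != b$bin_width) .fail("bin widths differ")
  if (!identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values)))
    .fail("chromosome partitions differ")
  x <- unlist(a$values, use.names = FALSE)
  y <- unlist(b$values, use.names = FALSE)
  if (var(x) == 0 || var(y) == 0) .fail("zero variance track; correlation undefined")
  cor(x, y)
}

#' Edge-to-edge gap between two intervals
#'
#' 0 if the intervals overlap or touch; otherwise the number of bases
#' strictly between them; `Inf` when they lie on different chromosomes.
#' Vectorized with recycling.
#'
#' @param a,b interval data.frames (or single rows).
#' @return numeric vector of gaps in bp.
#' @export
interval_gap <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(0, pmax(a$start[ia], b$start[ib]) - pmin(a$end[ia], b$end[ib]))
  gap[a$chrom[ia] != b$chrom[ib]] <- Inf
  gap
}
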