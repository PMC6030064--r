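#' @importFrom stats cor dist hclust cutree t.test rpois runif rnorm sd var
#' @importFrom utils head
NULL

# internal: stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovered expression modules against planted ones.
#' 1 means identical partitions (up to relabeling), ~0 chance agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .fail("label vectors differ in length")
  if (length(a) < 2) .fail("need at least 2 items")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
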