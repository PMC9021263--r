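# Local alignment (Smith-Waterman, affine gaps) and clipped-tail consensus.
# The aligner is used to confirm inserted consensus sequence against a
# mobile-element reference and to measure inverted-repeat similarity at
# inversion junctions.

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps via [Biostrings::pairwiseAlignment()].
#' A gap of length L costs `gap_open + L * gap_ext`. Identity is matches
#' divided by alignment columns (gap columns included).
#'
#' @param query,target Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (defaults 2,
#'   -4, -4, -2).
#' @return List with `score`, `query_range` and `target_range` (1-based
#'   inclusive), `cigar` (query-as-read vs target-as-reference: M/I/D),
#'   `n_match`, `columns`, `identity`. A zero-score alignment returns empty
#'   ranges and an empty CIGAR.
#' @export
local_align <- function(query, target, match = 2, mismatch = -4,
                        gap_open = 4, gap_ext = 2) {
  stopifnot(is.character(query), is.character(target),
            nzchar(query), nzchar(target))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(query, target, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = abs(gap_open),
                                      gapExtension = abs(gap_ext))
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, query_range = integer(0), target_range = integer(0),
                cigar = "", n_match = 0L, columns = 0L, identity = NA_real_))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(ap, "")[[1]]; sc_ <- strsplit(as_, "")[[1]]
  ops <- ifelse(pc == "-", "D", ifelse(sc_ == "-", "I", "M"))
  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  n_match <- sum(pc == sc_ & pc != "-")
  columns <- length(ops)
  list(score = sc,
       query_range = c(IRanges::start(Biostrings::pattern(pa)),
                       IRanges::end(Biostrings::pattern(pa))),
       target_range = c(IRanges::start(Biostrings::subject(pa)),
                        IRanges::end(Biostrings::subject(pa))),
       cigar = cigar, n_match = n_match, columns = columns,
       identity = n_match / columns)
}

#' Plurality consensus of soft-clipped tails
#'
#' Tails must be anchored at the clip start (column 1 = first clipped base
#' next to the junction). Consensus length is the median tail length
#' (rounded down for even counts); each column takes the plurality base
#' among tails covering it, ties broken lexicographically; columns covered
#' by fewer than `cons_min` tails are emitted as N.
#'
#' @param tails Character vector of clipped tail sequences (>= 1).
#' @param cons_min Minimum per-column coverage (default 2).
#' @return List with `consensus` and `support` (per-column count of tails
#'   agreeing with the consensus base).
#' @export
clipped_consensus <- function(tails, cons_min = 2L) {
  if (length(tails) == 0L) stop("clipped_consensus requires at least one tail")
  lens <- nchar(tails)
  L <- floor(stats::median(lens))
  if (L == 0L) return(list(consensus = "", support = integer(0)))
  mat <- matrix(NA_character_, nrow = length(tails), ncol = L)
  for (i in seq_along(tails)) {
    k <- min(lens[i], L)
    if (k > 0) mat[i, seq_len(k)] <- strsplit(substr(tails[i], 1, k), "")[[1]]
  }
  cons <- character(L); supp <- integer(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) < cons_min) { cons[j] <- "N"; supp[j] <- 0L; next }
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    cons[j] <- sort(top)[1]   # lexicographic tie-break
    supp[j] <- as.integer(tab[[cons[j]]])
  }
  list(consensus = paste(cons, collapse = ""), support = supp)
}
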