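# In-silico Cas9 digestion and per-allele expected-fragment prediction.
#
# A cut set over a sequence yields n+1 fragments that partition it exactly.
# Fragment predictions per SV class carry the alignment signature the
# targeted reads are expected to display against the reference:
#   contiguous        - single full-length match (reference-allele fragment)
#   gapped_two_segment- 5' match, reference gap, 3' match (deletion allele)
#   clipped_tail      - aligned prefix + soft-clipped inserted tail (insertion)
#   inverted_dual     - reference-orientation and inverted-orientation
#                       segments anchored at opposite junctions (inversion)

SIGNATURES <- c("contiguous", "gapped_two_segment", "clipped_tail", "inverted_dual")

#' Digest a sequence at a set of cut coordinates
#'
#' @param seq Single (optionally named) sequence string.
#' @param cuts Numeric vector of 0-based inter-base cut coordinates, strictly
#'   inside the sequence (`0 < cut < length`); duplicates collapse. A
#'   data.frame with a `cut` column is also accepted.
#' @return data.frame of fragments with `start`, `end` (0-based half-open),
#'   `length`, `seq`; the fragment sequences concatenate to the input.
#' @export
digest_sequence <- function(seq, cuts) {
  if (is.data.frame(cuts)) cuts <- cuts$cut
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  cuts <- sort(unique(as.numeric(cuts)))
  if (length(cuts) && (min(cuts) <= 0 || max(cuts) >= L))
    stop("cut coordinate outside (0, ", L, "): zero-length fragments are not allowed")
  bounds <- c(0, cuts, L)
  data.frame(
    start = bounds[-length(bounds)], end = bounds[-1],
    length = diff(bounds),
    seq = vapply(seq_len(length(bounds) - 1L), function(i)
      .subseq0(seq, bounds[i], bounds[i + 1L]), character(1)),
    stringsAsFactors = FALSE)
}

.frag_row <- function(sv_id, allele, length, length_max, signature, segments,
                      amplifiable = TRUE) {
  stopifnot(signature %in% SIGNATURES)
  structure(list(sv_id = sv_id, allele = allele, length = length,
                 length_max = length_max, signature = signature,
                 segments = segments, amplifiable = amplifiable),
            class = "expected_fragment")
}

#' @export
print.expected_fragment <- function(x, ...) {
  len <- if (is.na(x$length)) sprintf("<= %s", format(x$length_max, big.mark = ","))
         else format(x$length, big.mark = ",")
  cat(sprintf("<expected_fragment> %s %s allele: %s bp, %s [%s]\n", x$sv_id,
              x$allele, len, x$signature,
              paste(sprintf("%s:%d", x$segments$label, x$segments$length),
                    collapse = " + ")))
  invisible(x)
}

.seg <- function(...) {
  v <- c(...)
  data.frame(label = names(v), length = as.numeric(v), stringsAsFactors = FALSE)
}

#' Predict per-allele Cas9 fragments for an SV and its guide set
#'
#' Deletion (cuts a < b inside, c 3' of the interval): the reference allele
#' yields a `b - a` contiguous fragment; the deletion allele yields the a-c
#' span minus the deleted length — estimated from the optical interval, with
#' an upper bound `span - min_del` since the true deleted length is unknown
#' before sequencing. Insertion (element mode): aligned flank up to the
#' breakpoint plus the element prefix up to the consensus cut. Inversion:
#' `(start - f) + (end - p)` with flank + inverted segments.
#'
#' @param sv An [sv_record()].
#' @param guides The matching `guide_set`.
#' @param config A [pipeline_config()]; `min_del` bounds symbolic deletion
#'   fragment lengths.
#' @return List of `expected_fragment` objects.
#' @export
predict_fragments <- function(sv, guides, config = pipeline_config()) {
  stopifnot(inherits(sv, "sv_record"), inherits(guides, "guide_set"))
  if (guides$sv_id != sv$sv_id) stop("guide set does not match SV record")
  g <- guides$guides
  cut_of <- function(role) {
    i <- which(g$role == role)
    if (length(i) == 0L) stop("guide set for ", sv$sv_id, " missing role ", role)
    g$cut[i[1]]
  }
  iv <- sv$interval
  out <- list()
  if (sv$sv_type == "deletion") {
    a <- cut_of("flank_5p"); b <- cut_of("internal"); c <- cut_of("flank_3p")
    out$ref <- .frag_row(sv$sv_id, "ref", b - a, NA, "contiguous",
                         .seg(flank = b - a))
    span <- c - a
    est <- span - gi_length(iv)
    out$alt <- .frag_row(
      sv$sv_id, "alt", if (est > 0) est else NA, span - config$call$min_del,
      "gapped_two_segment",
      .seg(flank = max(0, iv$start - a), `deleted-absent` = 0,
           flank = max(0, c - iv$end)))
  } else if (sv$sv_type == "insertion") {
    a <- cut_of("flank_5p")
    if (any(g$role == "element")) {
      off <- g$consensus_offset[g$role == "element"][1]
      out$alt <- .frag_row(sv$sv_id, "alt", (iv$start - a) + off, NA,
                           "clipped_tail",
                           .seg(flank = iv$start - a, inserted = off))
    } else {
      c <- cut_of("flank_3p")
      out$ref <- .frag_row(sv$sv_id, "ref", c - a, NA, "contiguous",
                           .seg(flank = c - a))
      out$alt <- .frag_row(sv$sv_id, "alt", (c - a) + sv$size_estimate, NA,
                           "clipped_tail",
                           .seg(flank = iv$start - a,
                                inserted = sv$size_estimate,
                                flank = c - iv$start))
    }
  } else if (sv$sv_type == "inversion") {
    f <- cut_of("flank_5p"); p <- cut_of("internal")
    # on the non-inverted allele the two cuts may lie too far apart for the
    # PCR extension limit, in which case no reference-allele product exists
    out$ref <- .frag_row(sv$sv_id, "ref", p - f, NA, "contiguous",
                         .seg(flank = p - f),
                         amplifiable = !config$design$pcr_mode ||
                           (p - f) <= config$design$max_fragment)
    out$alt <- .frag_row(sv$sv_id, "alt", (iv$start - f) + (iv$end - p), NA,
                         "inverted_dual",
                         .seg(flank = iv$start - f, inverted = iv$end - p))
  } else {
    stop("fragment prediction not defined for sv_type '", sv$sv_type, "'")
  }
  unname(out)
}

#' Fraction of the genome captured by the expected fragments
#'
#' Symbolic (unknown-length) fragments contribute their upper bound.
#'
#' @param fragments List of `expected_fragment` objects.
#' @param genome_size Total genome size in bp.
#' @return Numeric fraction in `[0, 1]`.
#' @export
target_fraction <- function(fragments, genome_size) {
  stopifnot(genome_size > 0)
  if (length(fragments) == 0L) return(0)
  lens <- vapply(fragments, function(f)
    if (is.na(f$length)) f$length_max else f$length, numeric(1))
  sum(lens) / genome_size
}

#' Expand an expected fragment into its alignment signature
#'
#' @param fragment An `expected_fragment`.
#' @return List with `signature` and a data.frame of per-segment
#'   expectations (`label`, `length`, `aligned`, `orientation`).
#' @export
alignment_signature <- function(fragment) {
  stopifnot(inherits(fragment, "expected_fragment"))
  seg <- fragment$segments
  exp <- switch(fragment$signature,
    contiguous = data.frame(label = "flank", length = fragment$length,
                            aligned = TRUE, orientation = "+",
                            stringsAsFactors = FALSE),
    gapped_two_segment = data.frame(
      label = c("flank", "reference-gap", "flank"),
      length = c(seg$length[seg$label == "flank"][1], NA,
                 seg$length[seg$label == "flank"][2]),
      aligned = c(TRUE, FALSE, TRUE), orientation = c("+", NA, "+"),
      stringsAsFactors = FALSE),
    clipped_tail = {
      fl <- seg$length[seg$label == "flank"][1]
      data.frame(label = c("flank", "soft-clip"),
                 length = c(fl, sum(seg$length) - fl),
                 aligned = c(TRUE, FALSE), orientation = c("+", NA),
                 stringsAsFactors = FALSE)
    },
    inverted_dual = data.frame(
      label = c("flank", "inverted"),
      length = c(seg$length[seg$label == "flank"][1],
                 seg$length[seg$label == "inverted"][1]),
      aligned = c(TRUE, TRUE), orientation = c("+", "-"),
      stringsAsFactors = FALSE),
    stop("unknown signature '", fragment$signature, "'"))
  list(signature = fragment$signature, segments = exp)
}

#' Export expected fragments as TSV
#' @param fragments List of `expected_fragment` objects.
#' @param path Output path.
#' @export
write_fragment_table <- function(fragments, path) {
  rows <- do.call(rbind, lapply(fragments, function(f) {
    data.frame(sv_id = f$sv_id, allele = f$allele,
               length = if (is.na(f$length)) NA else f$length,
               length_max = f$length_max, signature = f$signature,
               amplifiable = f$amplifiable,
               segments = paste(sprintf("%s:%g", f$segments$label,
                                        f$segments$length), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
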