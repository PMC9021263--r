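# Breakpoint resolution from targeted-read alignments.
#
# Evidence conventions (all reported positions 1-based):
#  deletion  - 5' breakpoint = last aligned base of the 5' segment,
#              3' breakpoint = first aligned base of the 3' segment; both
#              from a CIGAR D >= min_del or from split segments with a
#              reference gap >= min_del and read-coordinate adjacency
#              <= adj_tol. Aggregation = median across supporting reads,
#              ties toward the smaller coordinate.
#  insertion - breakpoint = last reference base before the soft-clipped
#              tail (VCF-style placement); inserted consensus from the
#              clipped tails, optionally confirmed against an element
#              consensus by local alignment.
#  inversion - two junctions from opposite-strand segment pairs: for each
#              segment, the boundary away from its anchoring cut site
#              (last aligned base for a right boundary, first aligned base
#              for a left boundary).

.lo_median <- function(x) {
  # median with ties toward the smaller coordinate
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

.new_call <- function(sv_id, sv_type, breakpoints, sv_length, genotype,
                      support, inserted_consensus = NULL, flags = character(0)) {
  structure(list(sv_id = sv_id, sv_type = sv_type, breakpoints = breakpoints,
                 sv_length = sv_length, genotype = genotype, support = support,
                 inserted_consensus = inserted_consensus, flags = flags),
            class = "breakpoint_call")
}

.no_call <- function(sv_id, sv_type, support = c(ref = 0L, alt = 0L),
                     flags = character(0)) {
  .new_call(sv_id, sv_type,
            data.frame(chrom = character(), pos = numeric(),
                       side = character(), confidence = character(),
                       stringsAsFactors = FALSE),
            NA_real_, "no_call", support, flags = flags)
}

#' @export
print.breakpoint_call <- function(x, ...) {
  cat(sprintf("<breakpoint_call> %s (%s): genotype %s, support ref=%d alt=%d\n",
              x$sv_id, x$sv_type, x$genotype, x$support[["ref"]],
              x$support[["alt"]]))
  bp <- x$breakpoints
  for (i in seq_len(nrow(bp)))
    cat(sprintf("  %s breakpoint %s:%s [%s]\n", bp$side[i], bp$chrom[i],
                format(bp$pos[i], big.mark = ","), bp$confidence[i]))
  if (!is.na(x$sv_length)) cat("  sv_length:", x$sv_length, "bp\n")
  if (!is.null(x$inserted_consensus))
    cat(sprintf("  inserted consensus: %d bp\n", nchar(x$inserted_consensus)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Genotype a target from per-allele-class support
#'
#' An allele class is "present" when its support reaches `min_support`.
#' There is deliberately no allele-balance requirement: per-allele Cas9 cut
#' and amplification efficiency vary enormously in this assay, so a 171x/5x
#' imbalance is still a het.
#'
#' @param support Named vector/list with `ref` and `alt` counts.
#' @param config A [pipeline_config()] (`min_support`).
#' @return One of "het", "hom_alt", "hom_ref", "no_call".
#' @export
genotype_target <- function(support, config = pipeline_config()) {
  ms <- config$call$min_support
  ref_p <- support[["ref"]] >= ms
  alt_p <- support[["alt"]] >= ms
  if (ref_p && alt_p) "het"
  else if (alt_p) "hom_alt"
  else if (ref_p) "hom_ref"
  else "no_call"
}

.assigned_to <- function(groups, sv_id) {
  Filter(function(g) identical(g$assigned_sv, sv_id), groups$groups)
}

.cut_of <- function(guide_set, role) {
  g <- guide_set$guides
  i <- which(g$role == role)
  if (length(i) == 0L) return(NA_real_)
  g$cut[i[1]]
}

# deletion breakpoints inside one segment's CIGAR: D ops >= min_del
.cigar_big_dels <- function(seg, min_del) {
  tb <- .cigar_ops_table(seg$cigar)
  out <- list()
  ref <- seg$ref_start
  for (i in seq_len(nrow(tb))) {
    if (tb$op[i] %in% c("M", "=", "X")) ref <- ref + tb$len[i]
    else if (tb$op[i] %in% c("D", "N")) {
      if (tb$len[i] >= min_del)
        out[[length(out) + 1L]] <- c(bp5 = ref, bp3 = ref + tb$len[i] + 1)
      ref <- ref + tb$len[i]
    }
  }
  out
}

.has_n_run <- function(reference, chrom, start0, end0, n_run) {
  if (is.null(reference) || !chrom %in% names(reference)) return(FALSE)
  s <- .subseq0(reference[[chrom]], max(0, start0), min(nchar(reference[[chrom]]), end0))
  grepl(strrep("N", n_run), s, fixed = TRUE)
}

#' Call a deletion from assigned read groups
#'
#' @param groups `"alignment_groups"` after [assign_reads_to_targets()].
#' @param sv The [sv_record()] being typed.
#' @param guide_set Its `guide_set` (roles flank_5p/internal/flank_3p).
#' @param config A [pipeline_config()].
#' @param reference Optional named character vector; enables the
#'   reference-N-gap check.
#' @return A `breakpoint_call`.
#' @export
call_deletion <- function(groups, sv, guide_set, config = pipeline_config(),
                          reference = NULL) {
  ccfg <- config$call
  grps <- .assigned_to(groups, sv$sv_id)
  if (length(grps) == 0L) return(.no_call(sv$sv_id, "deletion"))
  cutA <- .cut_of(guide_set, "flank_5p")
  cutB <- .cut_of(guide_set, "internal")
  bp5s <- numeric(0); bp3s <- numeric(0)
  clip5 <- logical(0); clip3 <- logical(0)
  n_ref <- 0L; n_alt <- 0L
  chrom <- sv$interval$chrom
  for (g in grps) {
    seg <- g$segments[g$segments$chrom == chrom, , drop = FALSE]
    found_alt <- FALSE
    # within-segment deletion (CIGAR D >= min_del)
    for (s in seq_len(nrow(seg))) {
      dels <- .cigar_big_dels(seg[s, ], ccfg$min_del)
      if (length(dels)) {
        d <- dels[[1]]
        bp5s <- c(bp5s, d[["bp5"]]); bp3s <- c(bp3s, d[["bp3"]])
        clip5 <- c(clip5, FALSE); clip3 <- c(clip3, FALSE)
        found_alt <- TRUE
        break
      }
    }
    # split representation: two same-strand segments, reference gap >= min_del,
    # adjacent in read coordinates
    if (!found_alt && nrow(seg) >= 2L) {
      o <- order(seg$ref_start)
      for (k in seq_len(length(o) - 1L)) {
        s1 <- seg[o[k], ]; s2 <- seg[o[k + 1L], ]
        if (s1$strand != s2$strand) next
        gap <- s2$ref_start - s1$ref_end
        # read-coordinate gap between the aligned spans; bases in a positive
        # gap are soft-clipped in both records (unaligned wedge at the
        # junction, e.g. novel sequence over a reference N gap)
        adj <- if (s1$strand == "+") s2$read_start - s1$read_end
               else s1$read_start - s2$read_end
        wedge_ok <- adj > ccfg$adj_tol &&
          adj <= min(if (s1$strand == "+") s1$right_clip else s1$left_clip,
                     if (s2$strand == "+") s2$left_clip else s2$right_clip) +
            ccfg$adj_tol
        if (gap >= ccfg$min_del && (abs(adj) <= ccfg$adj_tol || wedge_ok)) {
          bp5s <- c(bp5s, s1$ref_end)        # 1-based last aligned base
          bp3s <- c(bp3s, s2$ref_start + 1)  # 1-based first aligned base
          # an unaligned wedge leaves the resumption side uncertain
          clip5 <- c(clip5, FALSE)
          clip3 <- c(clip3, adj > ccfg$clip_tol)
          found_alt <- TRUE
          break
        }
      }
    }
    if (found_alt) { n_alt <- n_alt + 1L; next }
    # reference-like: one contiguous segment matching the cutA-cutB fragment
    if (nrow(seg) == 1L && !is.na(cutA) && !is.na(cutB) &&
        abs(seg$ref_start[1] - cutA) <= ccfg$tol &&
        abs(seg$ref_end[1] - cutB) <= ccfg$tol)
      n_ref <- n_ref + 1L
  }
  support <- c(ref = n_ref, alt = n_alt)
  if (n_alt < ccfg$min_support && n_ref < ccfg$min_support)
    return(.no_call(sv$sv_id, "deletion", support))
  flags <- character(0)
  if (n_alt >= ccfg$min_support) {
    bp5 <- .lo_median(bp5s); bp3 <- .lo_median(bp3s)
    conf5 <- if (mean(clip5) > 0.5) "low" else "high"
    conf3 <- if (mean(clip3) > 0.5) "low" else "high"
    if (.has_n_run(reference, chrom, bp5, bp3 - 1, ccfg$n_run)) {
      flags <- c(flags, "reference_N_gap")
      conf3 <- "low"
    }
    bp <- data.frame(chrom = chrom, pos = c(bp5, bp3),
                     side = c("5p", "3p"), confidence = c(conf5, conf3),
                     stringsAsFactors = FALSE)
    sv_len <- if (conf5 == "high" && conf3 == "high") bp3 - bp5 - 1 else NA_real_
  } else {
    bp <- data.frame(chrom = character(), pos = numeric(), side = character(),
                     confidence = character(), stringsAsFactors = FALSE)
    sv_len <- NA_real_
  }
  .new_call(sv$sv_id, "deletion", bp, sv_len,
            genotype_target(support, config), support, flags = flags)
}

#' Call an insertion from assigned read groups
#'
#' @param groups `"alignment_groups"` after assignment.
#' @param sv The [sv_record()].
#' @param guide_set Its `guide_set`.
#' @param element_consensus Optional named character sequence; when given,
#'   the clipped-tail consensus is locally aligned to it and the call is
#'   flagged `element_confirmed` at identity >= `id_min` over >= `len_min`
#'   columns.
#' @param config A [pipeline_config()].
#' @param reference Unused; kept for interface symmetry.
#' @return A `breakpoint_call` with `inserted_consensus`.
#' @export
call_insertion <- function(groups, sv, guide_set, element_consensus = NULL,
                           config = pipeline_config(), reference = NULL) {
  ccfg <- config$call
  grps <- .assigned_to(groups, sv$sv_id)
  if (length(grps) == 0L) return(.no_call(sv$sv_id, "insertion"))
  chrom <- sv$interval$chrom
  right_bp <- numeric(0); right_tails <- character(0)
  left_bp <- numeric(0); left_tails <- character(0)
  contiguous <- list()  # candidates for reference-like classification
  for (g in grps) {
    seg <- g$segments[g$segments$chrom == chrom, , drop = FALSE]
    if (nrow(seg) == 0L) next
    s <- seg[which.max(seg$read_end - seg$read_start), ]  # main segment
    tb <- .cigar_ops_table(s$cigar)
    lead <- if (tb$op[1] == "S") tb$len[1] else 0L
    trail <- if (tb$op[nrow(tb)] == "S") tb$len[nrow(tb)] else 0L
    if (trail >= ccfg$min_clip && !is.na(s$seq) && nzchar(s$seq)) {
      # clip on the reference-right end: insertion after the last aligned base
      right_bp <- c(right_bp, s$ref_end)
      right_tails <- c(right_tails,
                       substr(s$seq, nchar(s$seq) - trail + 1L, nchar(s$seq)))
    } else if (lead >= ccfg$min_clip && !is.na(s$seq) && nzchar(s$seq)) {
      left_bp <- c(left_bp, s$ref_start)  # last ref base before the insert
      # tail read toward the junction: reverse-complement so column 1 abuts it
      left_tails <- c(left_tails, reverse_complement(substr(s$seq, 1L, lead)))
    } else if (nrow(seg) == 1L && lead < ccfg$min_clip && trail < ccfg$min_clip) {
      contiguous[[length(contiguous) + 1L]] <- s
    }
  }
  use_right <- length(right_bp) >= length(left_bp)
  bps <- if (use_right) right_bp else left_bp
  tails <- if (use_right) right_tails else left_tails
  n_alt <- length(bps)
  # reference-like = contiguous alignment spanning the called breakpoint
  # with margin; only meaningful once alt evidence fixes the position
  n_ref <- 0L
  if (n_alt > 0L) {
    bp_hat <- .lo_median(bps)
    for (s in contiguous)
      if (s$ref_start < bp_hat - ccfg$min_clip &&
          s$ref_end > bp_hat + ccfg$min_clip)
        n_ref <- n_ref + 1L
  }
  support <- c(ref = n_ref, alt = n_alt)
  if (n_alt == 0L)
    return(.no_call(sv$sv_id, "insertion", support))
  if (n_alt < ccfg$min_support && n_ref < ccfg$min_support)
    return(.no_call(sv$sv_id, "insertion", support))
  flags <- character(0)
  cons <- clipped_consensus(tails, ccfg$cons_min)
  if (!is.null(element_consensus)) {
    confirms <- function(q) {
      if (is.na(q) || nchar(q) < ccfg$len_min) return(FALSE)
      for (qq in c(q, reverse_complement(gsub("N", "A", q)))) {
        aln <- local_align(qq, element_consensus[[1]])
        if (!is.na(aln$identity) && aln$identity >= ccfg$id_min &&
            aln$columns >= ccfg$len_min) return(TRUE)
      }
      FALSE
    }
    ok <- confirms(cons$consensus)
    if (!ok) {
      # indel noise de-phases a columnar consensus; fall back to read-level
      # confirmation against the element, as the assay itself does
      samp <- tails[order(-nchar(tails))]
      samp <- samp[seq_len(min(5L, length(samp)))]
      ok <- mean(vapply(samp, confirms, logical(1))) >= 0.5
    }
    if (ok) flags <- c(flags, "element_confirmed")
  }
  bp <- data.frame(chrom = chrom, pos = .lo_median(bps), side = "insertion",
                   confidence = if (n_alt >= ccfg$min_support) "high" else "low",
                   stringsAsFactors = FALSE)
  .new_call(sv$sv_id, "insertion", bp, NA_real_,
            genotype_target(support, config), support,
            inserted_consensus = cons$consensus, flags = flags)
}

#' Call an inversion from assigned read groups
#'
#' Requires groups whose segments include opposite-strand alignments. For
#' each junction the reported position is the segment boundary away from its
#' anchoring cut site. When the sequence inward of the two called
#' breakpoints is near-identical in inverted orientation (assessed over
#' `rep_span` bp at identity >= `rep_id`), the `inverted_repeat_ambiguity`
#' flag is raised and both placements are reported.
#'
#' @param groups `"alignment_groups"` after assignment.
#' @param sv The [sv_record()].
#' @param guide_set Its `guide_set` (roles flank_5p/internal).
#' @param config A [pipeline_config()].
#' @param reference Optional; enables the inverted-repeat similarity check.
#' @return A `breakpoint_call`.
#' @export
call_inversion <- function(groups, sv, guide_set, config = pipeline_config(),
                           reference = NULL) {
  ccfg <- config$call
  grps <- .assigned_to(groups, sv$sv_id)
  if (length(grps) == 0L) return(.no_call(sv$sv_id, "inversion"))
  chrom <- sv$interval$chrom
  cut_f <- .cut_of(guide_set, "flank_5p")
  cut_p <- .cut_of(guide_set, "internal")
  cuts <- c(cut_f, cut_p)
  bp_int <- numeric(0); bp_dist <- numeric(0)
  n_ref <- 0L; n_alt <- 0L
  overlap_flag <- FALSE
  for (g in grps) {
    seg <- g$segments[g$segments$chrom == chrom, , drop = FALSE]
    if (nrow(seg) >= 2L && length(unique(seg$strand)) == 2L) {
      n_alt <- n_alt + 1L
      for (s in seq_len(nrow(seg))) {
        # which cut anchors this segment, and at which of its two boundaries
        d <- abs(outer(c(seg$ref_start[s], seg$ref_end[s]), cuts, "-"))
        hit <- which(d == min(d), arr.ind = TRUE)[1, ]
        # the reported junction is the boundary away from the anchor:
        # right boundary -> last aligned base; left boundary -> first
        bp <- if (hit[["row"]] == 1L) seg$ref_end[s] else seg$ref_start[s] + 1
        # flank-anchored segments delimit the internal junction; segments
        # anchored at the internal cut delimit the distal junction
        if (hit[["col"]] == 1L) bp_int <- c(bp_int, bp)
        else bp_dist <- c(bp_dist, bp)
      }
      # a read portion aligning at both junctions signals inverted repeats
      if (nrow(seg) > 2L) overlap_flag <- TRUE
      else {
        ov <- min(seg$read_end) - max(seg$read_start)
        len <- min(seg$read_end - seg$read_start)
        if (ov > 0.5 * len) overlap_flag <- TRUE
      }
    } else if (nrow(seg) == 1L && length(cuts) == 2L &&
               abs(seg$ref_start[1] - min(cuts)) <= ccfg$tol &&
               abs(seg$ref_end[1] - max(cuts)) <= ccfg$tol) {
      n_ref <- n_ref + 1L
    }
  }
  support <- c(ref = n_ref, alt = n_alt)
  if (n_alt == 0L || length(bp_int) == 0L || length(bp_dist) == 0L)
    return(.no_call(sv$sv_id, "inversion", support))
  if (n_alt < ccfg$min_support && n_ref < ccfg$min_support)
    return(.no_call(sv$sv_id, "inversion", support))
  b1 <- .lo_median(bp_int); b2 <- .lo_median(bp_dist)
  lo <- min(b1, b2); hi <- max(b1, b2)
  flags <- character(0)
  conf <- if (n_alt >= ccfg$min_support) "high" else "low"
  bp <- data.frame(chrom = chrom, pos = c(lo, hi),
                   side = c("junction_5p", "junction_3p"),
                   confidence = conf, stringsAsFactors = FALSE)
  # inverted-repeat similarity between the spans inward of the junctions
  if (!is.null(reference) && chrom %in% names(reference)) {
    L <- nchar(reference[[chrom]])
    span <- min(ccfg$rep_span, floor((hi - lo) / 2))
    if (span >= ccfg$len_min) {
      s5 <- .subseq0(reference[[chrom]], lo, min(L, lo + span))
      s3 <- .subseq0(reference[[chrom]], max(0, hi - span), hi)
      aln <- local_align(s5, reverse_complement(s3))
      if (!is.na(aln$identity) && aln$identity >= ccfg$rep_id &&
          aln$columns >= 0.8 * span)
        overlap_flag <- TRUE
    }
  }
  if (overlap_flag) {
    flags <- c(flags, "inverted_repeat_ambiguity")
    bp$confidence <- "ambiguous"
  }
  .new_call(sv$sv_id, "inversion", bp, hi - lo,
            genotype_target(support, config), support, flags = flags)
}

#' Insert a sequence into a reference at a breakpoint
#'
#' Builds the "custom reference" used to validate insertion calls: the
#' insert is placed immediately after the 1-based `breakpoint` base.
#' Re-aligned insertion-allele reads must become contiguous on this
#' reference.
#'
#' @param reference Named character vector.
#' @param chrom Chromosome to modify.
#' @param breakpoint 1-based position of the last reference base before the
#'   insert.
#' @param insert_seq Sequence to insert.
#' @return List with `sequences` (modified reference) and `map` (liftover
#'   blocks original <-> modified, same layout as the haplotype maps).
#' @export
build_custom_reference <- function(reference, chrom, breakpoint, insert_seq) {
  if (!chrom %in% names(reference)) stop("chromosome not in reference: ", chrom)
  L <- nchar(reference[[chrom]])
  if (breakpoint < 1 || breakpoint > L)
    stop("breakpoint out of range 1..", L)
  sv <- applied_sv("custom_insert", "insertion", chrom, breakpoint, breakpoint,
                   inserted_seq = insert_seq, zygosity = "hom")
  h <- apply_svs_to_reference(reference, list(sv))
  list(sequences = h$hap1, map = h$map1[[chrom]])
}

#' Per-target coverage summary
#'
#' Per-base depth over each expected fragment interval from the aligned
#' segments assigned to that target.
#'
#' @param groups `"alignment_groups"` after assignment.
#' @param target_intervals data.frame with `sv_id`, `chrom`, `start`, `end`
#'   (0-based half-open reference intervals).
#' @return List with `per_target` (data.frame sv_id, median, mean) and
#'   `median_coverage` (median of per-target medians).
#' @export
compute_target_coverage <- function(groups, target_intervals) {
  per <- lapply(seq_len(nrow(target_intervals)), function(i) {
    ti <- target_intervals[i, ]
    segs <- do.call(rbind, lapply(groups$groups, function(g) {
      s <- g$segments
      s[s$chrom == ti$chrom & s$ref_end > ti$start & s$ref_start < ti$end, ,
        drop = FALSE]
    }))
    width <- ti$end - ti$start
    if (is.null(segs) || nrow(segs) == 0L)
      return(data.frame(sv_id = ti$sv_id, median = 0, mean = 0))
    ir <- IRanges::IRanges(start = pmax(segs$ref_start, ti$start) + 1L,
                           end = pmin(segs$ref_end, ti$end))
    cov <- IRanges::coverage(ir, shift = -ti$start, width = width)
    v <- as.integer(cov)
    data.frame(sv_id = ti$sv_id, median = stats::median(v), mean = mean(v))
  })
  per <- do.call(rbind, per)
  list(per_target = per, median_coverage = stats::median(per$median))
}
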