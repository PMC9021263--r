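# Haplotype construction: applies SVs to a reference to produce the two
# sample haplotypes plus exact block-level liftover maps (reference <->
# haplotype, with strand for inverted blocks and unmapped blocks for
# insertions). het SVs edit haplotype 2 only; hom SVs edit both.

#' Describe one SV to apply to the reference
#'
#' @param sv_id Identifier.
#' @param sv_type "deletion", "insertion" or "inversion".
#' @param chrom Chromosome.
#' @param start,end 0-based half-open reference interval. For insertions
#'   `start == end` is the inter-base breakpoint (insert placed after
#'   1-based base `start`).
#' @param inserted_seq Required iff insertion.
#' @param zygosity "het" or "hom".
#' @return List of class `"applied_sv"` carrying 1-based
#'   `truth_breakpoints`: deletion = (last retained 5' base, first retained
#'   3' base); insertion = last reference base before the insert; inversion =
#'   (last base before the inverted block, last inverted base).
#' @export
applied_sv <- function(sv_id, sv_type, chrom, start, end,
                       inserted_seq = NULL, zygosity = c("het", "hom")) {
  sv_type <- match.arg(sv_type, c("deletion", "insertion", "inversion"))
  zygosity <- match.arg(zygosity)
  if (sv_type == "insertion") {
    if (start != end) stop("insertion interval must be zero-length (start == end)")
    if (is.null(inserted_seq) || !nzchar(inserted_seq))
      stop("insertion requires inserted_seq")
  } else {
    if (start >= end) stop("interval requires start < end")
    if (!is.null(inserted_seq)) stop("inserted_seq only valid for insertions")
  }
  tb <- switch(sv_type,
               deletion = c(start, end + 1),
               insertion = start,
               inversion = c(start, end))
  structure(list(sv_id = sv_id, sv_type = sv_type, chrom = chrom,
                 start = start, end = end, inserted_seq = inserted_seq,
                 zygosity = zygosity, truth_breakpoints = tb),
            class = "applied_sv")
}

# build block map + edited sequence for one chromosome given its SVs
.apply_chrom <- function(refseq, chrom, svs) {
  svs <- svs[order(vapply(svs, `[[`, numeric(1), "start"))]
  starts <- vapply(svs, `[[`, numeric(1), "start")
  ends <- vapply(svs, `[[`, numeric(1), "end")
  if (any(starts < 0) || any(ends > nchar(refseq)))
    stop("SV interval outside reference on ", chrom)
  if (length(svs) > 1L && any(starts[-1] < ends[-length(ends)]))
    stop("overlapping SVs on ", chrom)
  blocks <- list(); pieces <- character(0)
  pr <- 0; ph <- 0
  add_block <- function(rs, re, hs, he, strand, label) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      ref_start = rs, ref_end = re, hap_start = hs, hap_end = he,
      strand = strand, label = label, stringsAsFactors = FALSE)
  }
  for (sv in svs) {
    if (sv$start > pr) {  # identity block before this SV
      len <- sv$start - pr
      add_block(pr, sv$start, ph, ph + len, "+", "ref")
      pieces <- c(pieces, .subseq0(refseq, pr, sv$start))
      ph <- ph + len; pr <- sv$start
    }
    if (sv$sv_type == "deletion") {
      pr <- sv$end
    } else if (sv$sv_type == "insertion") {
      len <- nchar(sv$inserted_seq)
      add_block(NA, NA, ph, ph + len, "+", sv$sv_id)
      pieces <- c(pieces, sv$inserted_seq)
      ph <- ph + len
    } else {  # inversion: hap forward is the reverse complement of the block
      len <- sv$end - sv$start
      add_block(sv$start, sv$end, ph, ph + len, "-", sv$sv_id)
      pieces <- c(pieces, reverse_complement(.subseq0(refseq, sv$start, sv$end)))
      ph <- ph + len; pr <- sv$end
    }
  }
  if (pr < nchar(refseq)) {
    len <- nchar(refseq) - pr
    add_block(pr, nchar(refseq), ph, ph + len, "+", "ref")
    pieces <- c(pieces, .subseq0(refseq, pr, nchar(refseq)))
  }
  list(seq = paste(pieces, collapse = ""), map = do.call(rbind, blocks))
}

#' Apply SVs to a reference, producing two haplotypes with liftover maps
#'
#' @param ref Named character vector of reference sequences.
#' @param svs List of [applied_sv()] objects (non-overlapping per haplotype).
#' @return List of class `"sample_haplotypes"`: `hap1`, `hap2` (named
#'   character vectors), `map1`, `map2` (per-chromosome block tables), `svs`,
#'   `ref`.
#' @export
apply_svs_to_reference <- function(ref, svs) {
  stopifnot(all(vapply(svs, inherits, TRUE, "applied_sv")))
  chroms <- vapply(svs, `[[`, character(1), "chrom")
  if (!all(chroms %in% names(ref)))
    stop("SV chromosome(s) missing from reference: ",
         paste(setdiff(chroms, names(ref)), collapse = ", "))
  build_hap <- function(which_hap) {
    seqs <- ref; maps <- list()
    for (ch in names(ref)) {
      use <- svs[chroms == ch &
                 vapply(svs, function(s)
                   s$zygosity == "hom" || which_hap == 2L, logical(1))]
      if (length(use)) {
        r <- .apply_chrom(ref[[ch]], ch, use)
        seqs[[ch]] <- r$seq; maps[[ch]] <- r$map
      } else {
        maps[[ch]] <- data.frame(ref_start = 0, ref_end = nchar(ref[[ch]]),
                                 hap_start = 0, hap_end = nchar(ref[[ch]]),
                                 strand = "+", label = "ref",
                                 stringsAsFactors = FALSE)
      }
    }
    list(seqs = seqs, maps = maps)
  }
  h1 <- build_hap(1L); h2 <- build_hap(2L)
  structure(list(hap1 = h1$seqs, hap2 = h2$seqs, map1 = h1$maps, map2 = h2$maps,
                 svs = svs, ref = ref),
            class = "sample_haplotypes")
}

# lift a reference inter-base cut onto a haplotype; NA when it falls in a
# deleted region (the cut site no longer exists on that haplotype)
.lift_cut <- function(map, cut) {
  m <- map[!is.na(map$ref_start), , drop = FALSE]
  hit <- which(m$ref_start <= cut & cut <= m$ref_end)
  if (length(hit) == 0L) return(NA_real_)
  b <- m[hit[1], ]
  if (b$strand == "+") b$hap_start + (cut - b$ref_start)
  else b$hap_start + (b$ref_end - cut)
}

# inverse: haplotype interval [a, b) -> ordered reference-space sub-blocks
# (fragment-local coordinates attached); unmapped blocks keep ref NA
.hap_to_ref_blocks <- function(map, a, b) {
  out <- list()
  for (i in seq_len(nrow(map))) {
    blk <- map[i, ]
    lo <- max(a, blk$hap_start); hi <- min(b, blk$hap_end)
    if (lo >= hi) next
    if (is.na(blk$ref_start)) {
      out[[length(out) + 1L]] <- data.frame(
        frag_start = lo - a, frag_end = hi - a, ref_start = NA, ref_end = NA,
        strand = "+", label = blk$label, stringsAsFactors = FALSE)
    } else if (blk$strand == "+") {
      out[[length(out) + 1L]] <- data.frame(
        frag_start = lo - a, frag_end = hi - a,
        ref_start = blk$ref_start + (lo - blk$hap_start),
        ref_end = blk$ref_start + (hi - blk$hap_start),
        strand = "+", label = blk$label, stringsAsFactors = FALSE)
    } else {
      # hap forward runs along the reference block in reverse
      out[[length(out) + 1L]] <- data.frame(
        frag_start = lo - a, frag_end = hi - a,
        ref_start = blk$ref_end - (hi - blk$hap_start),
        ref_end = blk$ref_end - (lo - blk$hap_start),
        strand = "-", label = blk$label, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
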