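# SpCas9 protospacer search and SV-class-specific guide-set assembly.
#
# Geometry: 20-nt spacer immediately 5' of an NGG PAM; blunt cut 3 nt 5' of
# the PAM. Cut coordinates are 0-based inter-base points on the forward
# strand: a cut at c falls between bases c-1 and c (0-based), i.e. after
# 1-based base c.

T7_PROMOTER <- "TTCTAATACGACTCACTATAG"   # 21 nt
SGRNA_OVERLAP <- "GTTTTAGAGCTAGA"        # 14 nt
SGRNA_SCAFFOLD <- paste0("AAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCC",
                         "TTATTTTAACTTGCTATTTCTAGCTCTAAAAC")  # stored verbatim

#' Find SpCas9 protospacers in a window
#'
#' Scans both strands of `window` for 20-mers adjacent to an NGG PAM.
#' Spacers containing N are excluded. Forward hits have
#' `cut = pam_start - 3`; reverse hits (forward-strand context CCN + 20-mer)
#' have `cut = pam_start + 6`, both 0-based inter-base on the forward strand.
#'
#' @param seqs Named character vector of reference sequences.
#' @param window [gi()] search window; length >= 23.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open
#'   spacer interval on the forward strand), `strand`, `spacer` (protospacer
#'   orientation), `pam`, `cut` (0-based inter-base), `uniqueness` (NA until
#'   [screen_guides()]), sorted by `cut`.
#' @export
find_protospacers <- function(seqs, window) {
  stopifnot(inherits(window, "gi"))
  if (!window$chrom %in% names(seqs))
    stop("window chromosome '", window$chrom, "' not in reference")
  L <- nchar(seqs[[window$chrom]])
  if (window$start < 0 || window$end > L)
    stop("window outside sequence '", window$chrom, "' (length ", L, ")")
  if (gi_length(window) < 23) stop("window shorter than 23 bp")
  s <- .subseq0(seqs[[window$chrom]], window$start, window$end)
  w0 <- window$start
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), spacer = character(),
                      pam = character(), cut = integer(),
                      uniqueness = integer(), stringsAsFactors = FALSE)
  # forward: spacer(20, ACGT) + N-of-PAM(ACGT) + GG
  fwd <- as.integer(gregexpr("(?=[ACGT]{21}GG)", s, perl = TRUE)[[1]])
  fwd_df <- if (fwd[1] == -1L) empty else {
    sp0 <- w0 + fwd - 1L               # 0-based spacer start
    data.frame(chrom = window$chrom, start = sp0, end = sp0 + 20L,
               strand = "+", spacer = substring(s, fwd, fwd + 19L),
               pam = substring(s, fwd + 20L, fwd + 22L), cut = sp0 + 17L,
               uniqueness = NA_integer_, stringsAsFactors = FALSE)
  }
  # reverse: forward-strand context CC + N-of-PAM + 20-mer, all ACGT
  rev <- as.integer(gregexpr("(?=CC[ACGT]{21})", s, perl = TRUE)[[1]])
  rev_df <- if (rev[1] == -1L) empty else {
    pam0 <- w0 + rev - 1L              # 0-based CCN start on forward strand
    data.frame(chrom = window$chrom, start = pam0 + 3L, end = pam0 + 23L,
               strand = "-",
               spacer = reverse_complement(substring(s, rev + 3L, rev + 22L)),
               pam = reverse_complement(substring(s, rev, rev + 2L)),
               cut = pam0 + 6L, uniqueness = NA_integer_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(fwd_df, rev_df)
  out[order(out$cut, out$strand), , drop = FALSE]
}

.gc_fraction <- function(spacer) {
  nchar(gsub("[AT]", "", spacer)) / nchar(spacer)
}

.max_homopolymer <- function(spacer) {
  r <- rle(strsplit(spacer, "")[[1]])
  max(r$lengths)
}

# exact-match occurrence counts of constant-width patterns over both strands
# of the reference, in one dictionary pass
.count_occurrences <- function(patterns, ref_set) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
  pd_rc <- Biostrings::PDict(Biostrings::DNAStringSet(reverse_complement(patterns)))
  rowSums(Biostrings::vcountPDict(pd, ref_set)) +
    rowSums(Biostrings::vcountPDict(pd_rc, ref_set))
}

#' Screen protospacer candidates
#'
#' Keeps candidates whose spacer GC fraction lies in `[gc_min, gc_max]`,
#' whose longest homopolymer run is `<= max_homopolymer`, and whose
#' spacer+PAM 23-mer occurs exactly once in the reference (exact matching,
#' both strands). Order is preserved.
#'
#' @param candidates Output of [find_protospacers()].
#' @param reference Named character vector of reference sequences (the full
#'   uniqueness search space).
#' @param config A [pipeline_config()]; uses the `[design]` section.
#' @param check_uniqueness Set FALSE for element-consensus guides, which are
#'   deliberately multi-copy in the genome.
#' @return Filtered candidates with `uniqueness` filled in.
#' @export
screen_guides <- function(candidates, reference, config = pipeline_config(),
                          check_uniqueness = TRUE) {
  if (nrow(candidates) == 0L) return(candidates)
  dcfg <- config$design
  gc <- vapply(candidates$spacer, .gc_fraction, numeric(1))
  hp <- vapply(candidates$spacer, .max_homopolymer, numeric(1))
  keep <- gc >= dcfg$gc_min & gc <= dcfg$gc_max & hp <= dcfg$max_homopolymer
  candidates <- candidates[keep, , drop = FALSE]
  if (nrow(candidates) == 0L) return(candidates)
  if (check_uniqueness) {
    ref_set <- Biostrings::DNAStringSet(reference)
    pat <- paste0(candidates$spacer, candidates$pam)
    # express each site's 23-mer in forward-genome orientation before counting
    fwd23 <- ifelse(candidates$strand == "+", pat, reverse_complement(pat))
    candidates$uniqueness <- .count_occurrences(fwd23, ref_set)
    candidates <- candidates[candidates$uniqueness == 1, , drop = FALSE]
  }
  candidates
}

.scan_and_screen <- function(reference, chrom, lo, hi, config,
                             check_uniqueness = TRUE) {
  # scan a cut-coordinate window [lo, hi]; pad so protospacers whose cut
  # falls at the edges are still found, then filter on cut
  L <- nchar(reference[[chrom]])
  w <- gi(chrom, max(0, lo - 25), min(L, hi + 25))
  cand <- find_protospacers(reference, w)
  cand <- cand[cand$cut >= lo & cand$cut <= hi, , drop = FALSE]
  screen_guides(cand, reference, config, check_uniqueness)
}

.dist_to_N <- function(reference, chrom, cut, radius = 1000) {
  L <- nchar(reference[[chrom]])
  s <- .subseq0(reference[[chrom]], max(0, cut - radius), min(L, cut + radius))
  hits <- gregexpr("N", s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(radius)
  min(abs(max(0, cut - radius) + hits - 1L - cut))
}

.guide_row <- function(p, role, consensus_offset = NA_real_) {
  data.frame(role = role, chrom = p$chrom, cut = p$cut, strand = p$strand,
             spacer = p$spacer, pam = p$pam, start = p$start, end = p$end,
             uniqueness = p$uniqueness, consensus_offset = consensus_offset,
             stringsAsFactors = FALSE)
}

.new_guide_set <- function(sv, guides, element_name = NA_character_, notes = "") {
  if (anyDuplicated(guides$cut[!is.na(guides$cut)]) &&
      anyDuplicated(paste(guides$chrom, guides$cut)))
    stop("guide set for ", sv$sv_id, " has duplicate cut coordinates")
  structure(list(sv_id = sv$sv_id, sv_type = sv$sv_type, guides = guides,
                 element_name = element_name, notes = notes),
            class = "guide_set")
}

#' @export
print.guide_set <- function(x, ...) {
  cat(sprintf("<guide_set> %s (%s)%s\n", x$sv_id, x$sv_type,
              if (!is.na(x$element_name)) paste0(" element=", x$element_name) else ""))
  g <- x$guides
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-9s %s cut=%s (%s) %s %s\n", g$role[i], g$chrom[i],
                format(g$cut[i] + 1, big.mark = ","), g$strand[i],
                g$spacer[i], g$pam[i]))
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

.pick_best <- function(cand, target_fun, reference) {
  # minimize |achieved - target|; ties -> larger distance-to-N, then leftmost
  dev <- abs(target_fun(cand$cut))
  best <- which(dev == min(dev))
  if (length(best) > 1L) {
    dn <- vapply(best, function(i)
      .dist_to_N(reference, cand$chrom[i], cand$cut[i]), numeric(1))
    best <- best[dn == max(dn)]
    best <- best[which.min(cand$cut[best])]
  }
  cand[best[1L], , drop = FALSE]
}

#' Design the three-guide, two-pair layout for a deletion
#'
#' Guide A (`flank_5p`) anchors in the 5' window `[start - w_out,
#' start + w_in]` (interior placement allowed because optical intervals
#' over-extend past true breakpoints); guide B (`internal`) cuts inside the
#' interval so that the A-B reference-allele fragment is closest to
#' `ref_fragment_target`; guide C (`flank_3p`) cuts just 3' of the interval,
#' minimizing the A-C span. A is shared by both pairs. Under PCR mode the
#' A-C span must not exceed `max_fragment`.
#'
#' @param sv An [sv_record()] with `sv_type == "deletion"`.
#' @param reference Named character vector of sequences.
#' @param config A [pipeline_config()].
#' @return A `guide_set` with roles flank_5p, internal, flank_3p.
#' @export
design_deletion_guides <- function(sv, reference, config = pipeline_config()) {
  stopifnot(inherits(sv, "sv_record"))
  if (sv$sv_type != "deletion") stop("sv_type must be 'deletion'")
  dcfg <- config$design
  iv <- sv$interval
  candA <- .scan_and_screen(reference, iv$chrom,
                            max(1, iv$start - dcfg$w_out),
                            min(iv$end - 1, iv$start + dcfg$w_in), config)
  if (nrow(candA) == 0L) stop("no candidate guide for role flank_5p of ", sv$sv_id)
  candB <- .scan_and_screen(reference, iv$chrom, iv$start + 1, iv$end - 1, config)
  if (nrow(candB) == 0L) stop("no candidate guide for role internal of ", sv$sv_id)
  # joint A-B choice: reference-allele fragment closest to target
  grid <- expand.grid(a = seq_len(nrow(candA)), b = seq_len(nrow(candB)))
  grid$d <- candB$cut[grid$b] - candA$cut[grid$a]
  ok <- grid$d > 0
  if (dcfg$pcr_mode) ok <- ok & grid$d >= dcfg$min_fragment & grid$d <= dcfg$max_fragment
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L)
    stop("no feasible flank_5p/internal pair for ", sv$sv_id)
  dev <- abs(grid$d - dcfg$ref_fragment_target)
  pick <- grid[which(dev == min(dev)), , drop = FALSE]
  pick <- pick[order(candA$cut[pick$a], candB$cut[pick$b]), , drop = FALSE][1L, ]
  A <- candA[pick$a, , drop = FALSE]; B <- candB[pick$b, , drop = FALSE]
  L <- nchar(reference[[iv$chrom]])
  candC <- .scan_and_screen(reference, iv$chrom, iv$end,
                            min(L - 1, iv$end + dcfg$w_out), config)
  if (nrow(candC) == 0L) stop("no candidate guide for role flank_3p of ", sv$sv_id)
  span <- candC$cut - A$cut
  okC <- span > 0
  if (dcfg$pcr_mode) okC <- okC & span <= dcfg$max_fragment
  if (!any(okC))
    stop("spanning fragment exceeds max_fragment (", dcfg$max_fragment,
         " bp) for ", sv$sv_id, " under PCR mode")
  candC <- candC[okC, , drop = FALSE]
  C <- candC[which.min(candC$cut), , drop = FALSE]
  .new_guide_set(sv, rbind(.guide_row(A, "flank_5p"), .guide_row(B, "internal"),
                           .guide_row(C, "flank_3p")))
}

#' Design guides for an insertion
#'
#' With an element consensus (e.g. a LINE-1 consensus): a `flank_5p` guide
#' cutting within `[start - w_out, start]` plus an `element` guide chosen
#' from the consensus sequence. The element guide's cut position on the
#' reference is undefined; its offset within the consensus is recorded, and
#' it is chosen as far into the element as the PCR fragment bound allows.
#' Without a consensus: a flank pair whose expected mutant fragment
#' (reference span + `size_estimate`) must not exceed `max_fragment`.
#'
#' @param sv An [sv_record()] with `sv_type == "insertion"`.
#' @param reference Named character vector.
#' @param element_consensus Optional single named character sequence.
#' @param config A [pipeline_config()].
#' @return A `guide_set` with roles flank_5p + element, or flank_5p + flank_3p.
#' @export
design_insertion_guides <- function(sv, reference, element_consensus = NULL,
                                    config = pipeline_config()) {
  stopifnot(inherits(sv, "sv_record"))
  if (sv$sv_type != "insertion") stop("sv_type must be 'insertion'")
  dcfg <- config$design
  iv <- sv$interval
  candA <- .scan_and_screen(reference, iv$chrom,
                            max(1, iv$start - dcfg$w_out), iv$start, config)
  if (nrow(candA) == 0L) stop("no candidate guide for role flank_5p of ", sv$sv_id)
  if (!is.null(element_consensus)) {
    if (is.null(names(element_consensus))) names(element_consensus) <- "element"
    el_name <- names(element_consensus)[1]
    el_len <- nchar(element_consensus[[1]])
    if (el_len < 23) stop("element consensus shorter than 23 nt")
    candE <- find_protospacers(element_consensus, gi(el_name, 0, el_len))
    candE <- screen_guides(candE, reference, config, check_uniqueness = FALSE)
    if (nrow(candE) == 0L) stop("no candidate guide in element consensus for ", sv$sv_id)
    # tightest 5' flank, then the deepest element cut the PCR bound allows
    grid <- expand.grid(a = seq_len(nrow(candA)), e = seq_len(nrow(candE)))
    grid$flank <- iv$start - candA$cut[grid$a]
    grid$frag <- grid$flank + candE$cut[grid$e]
    ok <- rep(TRUE, nrow(grid))
    if (dcfg$pcr_mode) ok <- grid$frag >= dcfg$min_fragment & grid$frag <= dcfg$max_fragment
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid) == 0L)
      stop("no feasible flank/element pair within fragment bounds for ", sv$sv_id)
    grid <- grid[grid$flank == min(grid$flank), , drop = FALSE]
    pick <- grid[which.max(grid$frag), ]
    A <- candA[pick$a, , drop = FALSE]; E <- candE[pick$e, , drop = FALSE]
    gE <- .guide_row(E, "element", consensus_offset = E$cut)
    gE$chrom <- el_name; gE$cut <- NA_real_  # no reference cut coordinate
    .new_guide_set(sv, rbind(.guide_row(A, "flank_5p"), gE), element_name = el_name)
  } else {
    L <- nchar(reference[[iv$chrom]])
    candC <- .scan_and_screen(reference, iv$chrom, iv$end,
                              min(L - 1, iv$end + dcfg$w_out), config)
    if (nrow(candC) == 0L) stop("no candidate guide for role flank_3p of ", sv$sv_id)
    A <- candA[which.max(candA$cut), , drop = FALSE]   # tightest 5' flank
    C <- candC[which.min(candC$cut), , drop = FALSE]   # tightest 3' flank
    frag <- (C$cut - A$cut) + sv$size_estimate
    if (dcfg$pcr_mode && frag > dcfg$max_fragment)
      stop("flank-only targeting infeasible for ", sv$sv_id, ": expected mutant ",
           "fragment ", frag, " bp exceeds max_fragment ", dcfg$max_fragment, " bp")
    .new_guide_set(sv, rbind(.guide_row(A, "flank_5p"), .guide_row(C, "flank_3p")))
  }
}

#' Design the flank + internal guide pair for an inversion
#'
#' `flank_5p` cuts at f < start; `internal` cuts at p within
#' `internal_window` of the inversion's 3' end. In the inverted sample the
#' internal site moves next to the flank site, producing a fragment of
#' length `(start - f) + (end - p)`; the pair is chosen to bring that length
#' closest to `inv_fragment_target` within the PCR bounds.
#'
#' @param sv An [sv_record()] with `sv_type == "inversion"`.
#' @param reference Named character vector.
#' @param config A [pipeline_config()].
#' @return A `guide_set` with roles flank_5p, internal.
#' @export
design_inversion_guides <- function(sv, reference, config = pipeline_config()) {
  stopifnot(inherits(sv, "sv_record"))
  if (sv$sv_type != "inversion") stop("sv_type must be 'inversion'")
  dcfg <- config$design
  iv <- sv$interval
  candF <- .scan_and_screen(reference, iv$chrom,
                            max(1, iv$start - dcfg$w_out), iv$start - 1, config)
  if (nrow(candF) == 0L) stop("no candidate guide for role flank_5p of ", sv$sv_id)
  candP <- .scan_and_screen(reference, iv$chrom,
                            max(iv$start + 1, iv$end - dcfg$internal_window),
                            iv$end - 1, config)
  if (nrow(candP) == 0L)
    stop("no candidate guide in the internal window (", dcfg$internal_window,
         " bp from the 3' end) of ", sv$sv_id)
  grid <- expand.grid(f = seq_len(nrow(candF)), p = seq_len(nrow(candP)))
  grid$frag <- (iv$start - candF$cut[grid$f]) + (iv$end - candP$cut[grid$p])
  ok <- grid$frag > 0
  if (dcfg$pcr_mode) ok <- ok & grid$frag >= dcfg$min_fragment & grid$frag <= dcfg$max_fragment
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no feasible inversion fragment for ", sv$sv_id,
                             " within fragment bounds")
  dev <- abs(grid$frag - dcfg$inv_fragment_target)
  pick <- grid[which(dev == min(dev)), , drop = FALSE]
  pick <- pick[order(candF$cut[pick$f], candP$cut[pick$p]), , drop = FALSE][1L, ]
  .new_guide_set(sv, rbind(.guide_row(candF[pick$f, , drop = FALSE], "flank_5p"),
                           .guide_row(candP[pick$p, , drop = FALSE], "internal")))
}

#' Build the synthesis oligos for one guide
#'
#' The template oligo is the 55-mer T7 promoter (21 nt) + 20-nt spacer +
#' overlap (14 nt); the scaffold oligo is the fixed overlap-complementary
#' sequence shared by every guide in the single-pot synthesis.
#'
#' @param spacer 20-nt spacer sequence (protospacer orientation) or a
#'   single-row guide data.frame with a `spacer` column.
#' @return List with `template_oligo` (55 nt) and `scaffold_oligo`.
#' @export
emit_synthesis_oligos <- function(spacer) {
  if (is.data.frame(spacer)) spacer <- spacer$spacer[1]
  stopifnot(is.character(spacer), length(spacer) == 1L)
  if (nchar(spacer) != 20L) stop("spacer must be exactly 20 nt, got ", nchar(spacer))
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over {A,C,G,T}")
  list(template_oligo = paste0(T7_PROMOTER, spacer, SGRNA_OVERLAP),
       scaffold_oligo = SGRNA_SCAFFOLD)
}

#' Export a guide panel as TSV
#'
#' One row per guide: sv_id, role, chrom, 1-based cut coordinate, strand,
#' spacer, PAM, uniqueness, consensus offset (element guides), template
#' oligo.
#'
#' @param guide_sets List of `guide_set` objects.
#' @param path Output path.
#' @export
write_guide_panel <- function(guide_sets, path) {
  rows <- do.call(rbind, lapply(guide_sets, function(gs) {
    g <- gs$guides
    data.frame(sv_id = gs$sv_id, role = g$role, chrom = g$chrom,
               cut_1based = ifelse(is.na(g$cut), NA, g$cut + 1),
               strand = g$strand, spacer = g$spacer, pam = g$pam,
               uniqueness = g$uniqueness,
               consensus_offset = g$consensus_offset,
               template_oligo = vapply(g$spacer, function(s)
                 emit_synthesis_oligos(s)$template_oligo, character(1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
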