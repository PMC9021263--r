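# Alignment ingest. SAM/BAM goes through Rsamtools (SAM is converted with
# asBam first); PAF-with-CIGAR ("cg" tag) is parsed directly since no R
# reader exists for it. Records are grouped per read into
# read-alignment groups holding per-segment geometry in both reference and
# read coordinates.

.cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

.cigar_ops_table <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# one segment row from SAM-style fields (pos is 1-based)
.segment_row <- function(read_id, chrom, pos, strand, cigar, is_supp, nm, seq) {
  tb <- .cigar_ops_table(cigar)
  ref_w <- sum(tb$len[tb$op %in% c("M", "D", "N", "=", "X")])
  q_aln <- sum(tb$len[tb$op %in% c("M", "I", "=", "X")])
  lead <- if (nrow(tb) && tb$op[1] %in% c("S", "H")) tb$len[1] else 0L
  trail <- if (nrow(tb) && tb$op[nrow(tb)] %in% c("S", "H")) tb$len[nrow(tb)] else 0L
  qlen <- lead + q_aln + trail
  # read-orientation clip/interval: stored order equals read order on "+",
  # reversed on "-"
  if (strand == "+") { lc <- lead; rc <- trail } else { lc <- trail; rc <- lead }
  data.frame(read_id = read_id, chrom = chrom,
             ref_start = pos - 1L, ref_end = pos - 1L + ref_w,
             strand = strand, cigar = cigar,
             left_clip = lc, right_clip = rc,
             read_start = lc, read_end = lc + q_aln, read_len = qlen,
             is_supplementary = is_supp, nm = nm, seq = seq,
             stringsAsFactors = FALSE)
}

#' Load alignments into read-alignment groups
#'
#' @param path SAM, BAM, or PAF file.
#' @param dialect `"sam_bam"` or `"paf"`. PAF records must carry a `cg:Z`
#'   CIGAR tag.
#' @return List of class `"alignment_groups"`: `groups` (per read: `read_id`,
#'   `segments` data.frame sorted by read coordinate, `assigned_sv`,
#'   `allele_class`), `n_unmapped` (dropped records).
#' @export
load_alignments <- function(path, dialect = c("sam_bam", "paf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  segs <- list(); n_unmapped <- 0L
  if (dialect == "sam_bam") {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      dest <- tempfile()
      bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                               indexDestination = FALSE))
    }
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"),
      tag = c("NM", "SA"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    mapped <- bitwAnd(x$flag, 4L) == 0L & !is.na(x$pos)
    n_unmapped <- sum(!mapped)
    if (any(mapped)) {
      seq_chr <- as.character(x$seq)
      nm <- if (!is.null(x$tag$NM)) x$tag$NM else rep(NA_integer_, length(mapped))
      idx <- which(mapped)
      segs <- lapply(idx, function(i) .segment_row(
        x$qname[i], as.character(x$rname[i]), x$pos[i],
        if (bitwAnd(x$flag[i], 16L) > 0L) "-" else "+",
        x$cigar[i], bitwAnd(x$flag[i], 2048L) > 0L, nm[i], seq_chr[i]))
    }
  } else {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      if (!nzchar(lines[[i]])) next
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 12L) stop("malformed PAF record at line ", i)
      tags <- f[-(1:12)]
      cg <- tags[startsWith(tags, "cg:Z:")]
      if (length(cg) == 0L)
        stop("PAF record at line ", i, " lacks a cg (CIGAR) tag")
      cigar <- sub("^cg:Z:", "", cg[1])
      nm_t <- tags[startsWith(tags, "NM:i:")]
      nm <- if (length(nm_t)) as.integer(sub("^NM:i:", "", nm_t[1])) else NA_integer_
      qlen <- as.integer(f[2]); qstart <- as.integer(f[3]); qend <- as.integer(f[4])
      strand <- f[5]
      # synthesize clips from query coordinates so geometry matches SAM ingest
      lead <- if (strand == "+") qstart else qlen - qend
      trail <- if (strand == "+") qlen - qend else qstart
      cig <- paste0(if (lead > 0) paste0(lead, "S") else "", cigar,
                    if (trail > 0) paste0(trail, "S") else "")
      segs[[length(segs) + 1L]] <- .segment_row(
        f[1], f[6], as.integer(f[8]) + 1L, strand, cig,
        FALSE, nm, NA_character_)
    }
  }
  if (length(segs) == 0L)
    return(structure(list(groups = list(), n_unmapped = n_unmapped),
                     class = "alignment_groups"))
  tab <- do.call(rbind, segs)
  groups <- lapply(split(tab, tab$read_id), function(g) {
    g <- g[order(g$read_start, g$ref_start), , drop = FALSE]
    if (sum(!g$is_supplementary) > 1L)
      g$is_supplementary[which(!g$is_supplementary)[-1]] <- TRUE
    list(read_id = g$read_id[1], segments = g,
         assigned_sv = NA_character_, allele_class = NA_character_)
  })
  structure(list(groups = unname(groups), n_unmapped = n_unmapped),
            class = "alignment_groups")
}

#' @export
print.alignment_groups <- function(x, ...) {
  nseg <- sum(vapply(x$groups, function(g) nrow(g$segments), numeric(1)))
  cat(sprintf("<alignment_groups> %d read group(s), %d segment(s), %d unmapped dropped\n",
              length(x$groups), nseg, x$n_unmapped))
  invisible(x)
}

#' Assign read groups to designed targets
#'
#' A group is assigned to the SV whose guide set has a cut site within `tol`
#' of any segment boundary (same chromosome); ties go to the smallest
#' boundary distance. Unassigned groups are labelled `"background"`.
#'
#' @param groups An `"alignment_groups"` object.
#' @param guide_sets List of `guide_set` objects.
#' @param tol Distance tolerance in bp (default 100).
#' @return The groups with `assigned_sv` filled in.
#' @export
assign_reads_to_targets <- function(groups, guide_sets, tol = 100) {
  stopifnot(inherits(groups, "alignment_groups"), tol >= 0)
  cuts <- do.call(rbind, lapply(guide_sets, function(gs) {
    g <- gs$guides[!is.na(gs$guides$cut), , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    data.frame(sv_id = gs$sv_id, chrom = g$chrom, cut = g$cut,
               stringsAsFactors = FALSE)
  }))
  groups$groups <- lapply(groups$groups, function(grp) {
    seg <- grp$segments
    best_sv <- "background"; best_d <- Inf
    for (s in seq_len(nrow(seg))) {
      for (b in c(seg$ref_start[s], seg$ref_end[s])) {
        hit <- cuts$chrom == seg$chrom[s]
        if (!any(hit)) next
        d <- abs(cuts$cut[hit] - b)
        if (min(d) < best_d) {
          best_d <- min(d)
          best_sv <- cuts$sv_id[hit][which.min(d)]
        }
      }
    }
    grp$assigned_sv <- if (best_d <= tol) best_sv else "background"
    grp
  })
  groups
}
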