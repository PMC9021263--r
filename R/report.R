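# Standard-format outputs: VCF 4.2 with symbolic SV ALTs, and a per-SV
# report table combining design, prediction and call results.

#' Write breakpoint calls as VCF 4.2
#'
#' Symbolic ALTs `<DEL>/<INS>/<INV>`; POS is the last reference base before
#' the event; INFO carries SVTYPE, END, SVLEN (negative for deletions),
#' SUPPORT (ref,alt), BPCONF and FLAGS; FORMAT is GT:DP. Calls with any
#' low-confidence or ambiguous breakpoint, or without a genotype, get
#' FILTER=LowConf.
#'
#' @param calls List of `breakpoint_call` objects.
#' @param reference Named character vector (declares contigs and provides
#'   REF bases) or a named numeric vector of contig lengths.
#' @param path Output path.
#' @export
write_vcf <- function(calls, reference, path) {
  ref_is_seq <- is.character(reference)
  contigs <- names(reference)
  contig_len <- if (ref_is_seq) vapply(reference, nchar, numeric(1))
                else as.numeric(reference)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=castsv",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(contig_len)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length (negative for deletions)\">",
    "##INFO=<ID=SUPPORT,Number=2,Type=Integer,Description=\"Reads supporting ref,alt allele classes\">",
    "##INFO=<ID=BPCONF,Number=.,Type=String,Description=\"Per-breakpoint confidence\">",
    "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Caller flags\">",
    "##FILTER=<ID=LowConf,Description=\"Low-confidence, ambiguous or unresolved call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  rows <- list()
  for (cl in calls) {
    if (!inherits(cl, "breakpoint_call")) stop("write_vcf expects breakpoint_call objects")
    bp <- cl$breakpoints
    if (nrow(bp) == 0L) next
    chrom <- bp$chrom[1]
    if (!chrom %in% contigs) stop("call ", cl$sv_id, " on undeclared contig ", chrom)
    pos <- min(bp$pos)
    svtype <- switch(cl$sv_type, deletion = "DEL", insertion = "INS",
                     inversion = "INV",
                     stop("unsupported sv_type for VCF: ", cl$sv_type))
    end <- switch(cl$sv_type,
                  deletion = max(bp$pos) - 1,  # last deleted base
                  insertion = pos,
                  inversion = max(bp$pos))
    svlen <- switch(cl$sv_type,
                    deletion = if (is.na(cl$sv_length)) NA else -cl$sv_length,
                    insertion = if (is.null(cl$inserted_consensus)) NA
                                else nchar(cl$inserted_consensus),
                    inversion = if (is.na(cl$sv_length)) NA else cl$sv_length)
    info <- c(sprintf("SVTYPE=%s", svtype),
              sprintf("END=%d", as.integer(end)),
              if (!is.na(svlen)) sprintf("SVLEN=%d", as.integer(svlen)),
              sprintf("SUPPORT=%d,%d", cl$support[["ref"]], cl$support[["alt"]]),
              sprintf("BPCONF=%s", paste(bp$confidence, collapse = ",")),
              if (length(cl$flags)) sprintf("FLAGS=%s", paste(cl$flags, collapse = ",")))
    gt <- switch(cl$genotype, het = "0/1", hom_alt = "1/1", hom_ref = "0/0",
                 no_call = "./.")
    lowconf <- any(bp$confidence != "high") || cl$genotype == "no_call"
    refbase <- if (ref_is_seq) substr(reference[[chrom]], pos, pos) else "N"
    if (!nzchar(refbase)) refbase <- "N"
    rows[[length(rows) + 1L]] <- list(
      chrom = chrom, pos = pos,
      line = paste(chrom, format(pos, scientific = FALSE), cl$sv_id, refbase,
                   paste0("<", svtype, ">"), ".",
                   if (lowconf) "LowConf" else "PASS",
                   paste(info, collapse = ";"),
                   "GT:DP",
                   sprintf("%s:%d", gt, sum(cl$support)), sep = "\t"))
  }
  if (length(rows)) {
    ord <- order(match(vapply(rows, `[[`, character(1), "chrom"), contigs),
                 vapply(rows, `[[`, numeric(1), "pos"))
    body <- vapply(rows[ord], `[[`, character(1), "line")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the per-SV report table
#'
#' One row per SV: design coordinates (1-based), expected and observed
#' fragment lengths, breakpoints, genotype, support, flags and median
#' coverage. Missing coverage becomes NA, not an error.
#'
#' @param calls List of `breakpoint_call` objects.
#' @param guide_sets List of `guide_set` objects (same sv_ids).
#' @param fragments List of `expected_fragment` objects.
#' @param coverage Optional output of [compute_target_coverage()].
#' @param path Output path.
#' @export
write_report_tsv <- function(calls, guide_sets, fragments, coverage = NULL,
                             path) {
  gs_ids <- vapply(guide_sets, `[[`, character(1), "sv_id")
  rows <- lapply(calls, function(cl) {
    i <- match(cl$sv_id, gs_ids)
    if (is.na(i)) stop("no guide set for sv_id ", cl$sv_id)
    gs <- guide_sets[[i]]
    g <- gs$guides
    frs <- Filter(function(f) f$sv_id == cl$sv_id, fragments)
    exp_len <- paste(vapply(frs, function(f)
      sprintf("%s:%s", f$allele,
              if (is.na(f$length)) sprintf("<=%g", f$length_max)
              else sprintf("%g", f$length)), character(1)), collapse = ";")
    bp <- cl$breakpoints
    cov <- NA_real_
    if (!is.null(coverage)) {
      j <- match(cl$sv_id, coverage$per_target$sv_id)
      if (!is.na(j)) cov <- coverage$per_target$median[j]
    }
    data.frame(
      sv_id = cl$sv_id, sv_type = cl$sv_type,
      guide_cuts_1based = paste(sprintf("%s:%s", g$role,
        ifelse(is.na(g$cut), "element", format(g$cut + 1, scientific = FALSE))),
        collapse = ";"),
      expected_fragments = exp_len,
      breakpoints_1based = if (nrow(bp)) paste(sprintf("%s:%s:%s", bp$side,
        bp$chrom, format(bp$pos, scientific = FALSE)), collapse = ";") else "NA",
      sv_length = if (is.na(cl$sv_length)) NA else cl$sv_length,
      genotype = cl$genotype,
      support_ref = cl$support[["ref"]], support_alt = cl$support[["alt"]],
      flags = if (length(cl$flags)) paste(cl$flags, collapse = ",") else ".",
      median_coverage = cov,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
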