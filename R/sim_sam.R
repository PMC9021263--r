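# Truth alignments: reference-space SAM records computed through the known
# haplotype liftover, standing in for an external aligner during testing.
#
# Per read, the fragment's haplotype interval decomposes into liftover
# blocks. Mapped blocks on the same strand separated by a reference gap
# <= split_threshold merge into one record with a D op (the CIGAR-deletion
# representation); larger gaps split into primary + supplementary records
# linked by SA tags (the split-read representation). Interior unmapped
# blocks (inserted sequence crossed by a background read) merge as I ops
# when short; terminal unmapped blocks (targeted insertion tails) become
# soft clips. Inverted blocks always form their own opposite-strand record.

# expand a mapped block's per-base edit profile into alignment units
# ("M" match/sub, "D" deleted base, "I" inserted base), fragment order
.block_units <- function(base_ops, ins, a, b) {
  bo <- base_ops[(a + 1):b]
  bi <- ins[(a + 1):b]
  counts <- 1L + bi
  out <- rep("I", sum(counts))
  out[cumsum(counts) - bi] <- ifelse(bo == "D", "D", "M")
  out
}

# read-consumed bases of a fragment range under the edit profile
.range_qlen <- function(base_ops, ins, a, b) {
  if (b <= a) return(0L)
  sum(base_ops[(a + 1):b] != "D") + sum(ins[(a + 1):b])
}

# simulated edit count (NM) within a fragment range
.range_nm <- function(base_ops, ins, a, b) {
  if (b <= a) return(0L)
  sum(base_ops[(a + 1):b] != "M") + sum(ins[(a + 1):b])
}

.units_to_cigar <- function(units) {
  r <- rle(units)
  paste0(r$lengths, r$values, collapse = "")
}

# assemble one SAM record from a run of liftover blocks (indices into blocks)
.build_record <- function(read, blocks, idx) {
  mapped <- idx[!is.na(blocks$ref_start[idx])]
  sigma <- blocks$strand[mapped[1]]
  units <- character(0)
  nm <- 0L
  prev <- NULL
  for (i in idx) {
    blk <- blocks[i, ]
    if (is.na(blk$ref_start)) {  # interior unmapped -> insertion units
      q <- .range_qlen(read$base_ops, read$ins, blk$frag_start, blk$frag_end)
      units <- c(units, rep("I", q))
    } else {
      if (!is.null(prev)) {      # structural reference gap -> D units
        gap <- if (sigma == "+") blk$ref_start - prev$ref_end
               else prev$ref_start - blk$ref_end
        if (gap > 0) units <- c(units, rep("D", gap))
      }
      units <- c(units, .block_units(read$base_ops, read$ins,
                                     blk$frag_start, blk$frag_end))
      nm <- nm + .range_nm(read$base_ops, read$ins, blk$frag_start, blk$frag_end)
      prev <- blk
    }
  }
  if (sigma == "-") units <- rev(units)  # ref-forward order
  # trim leading/trailing D (alignment cannot start or end with a deletion);
  # leading/trailing I become part of the soft clips
  lead_d <- 0L
  while (length(units) && units[1] == "D") { units <- units[-1]; lead_d <- lead_d + 1L }
  while (length(units) && units[length(units)] == "D") units <- units[-length(units)]
  lead_i <- 0L
  while (length(units) && units[1] == "I") { units <- units[-1]; lead_i <- lead_i + 1L }
  trail_i <- 0L
  while (length(units) && units[length(units)] == "I") {
    units <- units[-length(units)]; trail_i <- trail_i + 1L
  }
  if (length(units) == 0L) return(NULL)
  # leading D trimming advances POS regardless of strand (units are already
  # in reference-forward order at this point)
  pos0 <- min(blocks$ref_start[mapped]) + lead_d
  # clips: read-consumed bases outside the record's fragment range
  A <- blocks$frag_start[idx[1]]; B <- blocks$frag_end[idx[length(idx)]]
  clip_before <- .range_qlen(read$base_ops, read$ins, 0, A)
  frag_len <- length(read$base_ops)
  clip_after <- .range_qlen(read$base_ops, read$ins, B, frag_len)
  if (sigma == "+") {
    s_left <- clip_before + lead_i; s_right <- clip_after + trail_i
  } else {
    s_left <- clip_after + lead_i; s_right <- clip_before + trail_i
  }
  cig <- .units_to_cigar(units)
  if (s_left > 0) cig <- paste0(s_left, "S", cig)
  if (s_right > 0) cig <- paste0(cig, s_right, "S")
  flag16 <- (sigma == "+") != (read$strand == "+")
  list(chrom = blocks$label_chrom[idx[1]], pos0 = pos0, sigma = sigma,
       flag16 = flag16, cigar = cig, nm = nm,
       aligned_q = sum(units != "D"))
}

#' Emit truth alignments for a simulated read set as SAM
#'
#' Computes reference-space alignments for every read through the haplotype
#' liftover, with CIGARs consistent with the simulated edits and `NM` equal
#' to the simulated edit count of each record's aligned span. Reads falling
#' entirely inside inserted sequence are emitted unmapped. Output is
#' coordinate-sorted with a full header.
#'
#' @param read_set A `read_set` from [simulate_reads()].
#' @param haplotypes The `"sample_haplotypes"` the reads were simulated from.
#' @param path Output SAM path.
#' @param split_threshold Deleted span (bp) above which a deletion is
#'   represented as split records rather than a CIGAR D op (default from
#'   `pipeline_config()$simulate$split_threshold`).
#' @return Invisible `path`.
#' @export
emit_truth_alignments <- function(read_set, haplotypes, path,
                                  split_threshold = 10000) {
  stopifnot(inherits(read_set, "read_set"),
            inherits(haplotypes, "sample_haplotypes"))
  recs <- list()
  for (rid in read_set$reads$read_id) {
    tr <- read_set$truth[[rid]]
    if (is.null(tr)) stop("read without truth: ", rid)
    maps <- if (tr$hap == 1L) haplotypes$map1 else haplotypes$map2
    blocks <- .hap_to_ref_blocks(maps[[tr$chrom]], tr$frag_start, tr$frag_end)
    blocks$label_chrom <- tr$chrom
    row_of <- which(read_set$reads$read_id == rid)
    seq_read <- read_set$reads$seq[row_of]
    # SEQ as stored: fragment orientation for + records, revcomp for -
    seq_frag <- if (tr$strand == "+") seq_read else reverse_complement(seq_read)

    # group blocks into records
    groups <- list(); cur <- integer(0)
    n <- nrow(blocks)
    flush <- function() {
      if (length(cur) && any(!is.na(blocks$ref_start[cur])))
        groups[[length(groups) + 1L]] <<- cur
      cur <<- integer(0)
    }
    i <- 1L
    while (i <= n) {
      blk <- blocks[i, ]
      if (is.na(blk$ref_start)) {
        joinable <- length(cur) > 0L && i < n &&
          !is.na(blocks$ref_start[i + 1L]) &&
          blocks$strand[i + 1L] == blocks$strand[cur[length(cur)]] &&
          blocks$strand[i + 1L] == "+" &&
          (blk$frag_end - blk$frag_start) <= split_threshold &&
          blocks$ref_start[i + 1L] == blocks$ref_end[cur[length(cur)]]
        if (joinable) { cur <- c(cur, i) } else flush()
      } else if (length(cur) == 0L) {
        cur <- i
      } else {
        last <- cur[length(cur)]
        last_mapped <- if (is.na(blocks$ref_start[last])) cur[length(cur) - 1L] else last
        same_plus <- blk$strand == "+" && blocks$strand[last_mapped] == "+"
        gap <- blk$ref_start - blocks$ref_end[last_mapped]
        if (same_plus && gap >= 0 && gap <= split_threshold) cur <- c(cur, i)
        else { flush(); cur <- i }
      }
      i <- i + 1L
    }
    flush()

    if (length(groups) == 0L) {  # fully inside inserted sequence: unmapped
      recs[[length(recs) + 1L]] <- list(
        qname = rid, flag = 4L, rname = "*", pos = 0L, mapq = 0L, cigar = "*",
        seq = seq_read, qual = strrep("I", nchar(seq_read)), tags = character(0),
        sort_chrom = "~", sort_pos = 0)
      next
    }
    rr <- Filter(Negate(is.null),
                 lapply(groups, function(g) .build_record(tr, blocks, g)))
    if (length(rr) == 0L) next
    primary <- which.max(vapply(rr, `[[`, numeric(1), "aligned_q"))
    sa_str <- vapply(rr, function(r)
      sprintf("%s,%d,%s,%s,60,%d;", r$chrom, r$pos0 + 1L,
              if (r$flag16) "-" else "+", r$cigar, r$nm), character(1))
    for (j in seq_along(rr)) {
      r <- rr[[j]]
      flag <- 0L
      if (r$flag16) flag <- flag + 16L
      if (j != primary) flag <- flag + 2048L
      seq_store <- if (r$sigma == "+") seq_frag else reverse_complement(seq_frag)
      tags <- sprintf("NM:i:%d", r$nm)
      if (length(rr) > 1L)
        tags <- c(tags, paste0("SA:Z:", paste(sa_str[-j], collapse = "")))
      recs[[length(recs) + 1L]] <- list(
        qname = rid, flag = flag, rname = r$chrom, pos = r$pos0 + 1L,
        mapq = 60L, cigar = r$cigar, seq = seq_store,
        qual = strrep("I", nchar(seq_store)), tags = tags,
        sort_chrom = r$chrom, sort_pos = r$pos0)
    }
  }
  # header + coordinate sort
  chroms <- names(haplotypes$ref)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      vapply(haplotypes$ref, nchar, numeric(1))),
              "@PG\tID:castsv\tPN:castsv")
  key_chrom <- vapply(recs, function(r) r$sort_chrom, character(1))
  key_pos <- vapply(recs, function(r) as.numeric(r$sort_pos), numeric(1))
  ord <- order(match(key_chrom, c(chroms, "~")), key_pos)
  lines <- vapply(recs[ord], function(r)
    paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
            r$seq, r$qual, r$tags), collapse = "\t"), character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
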