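# Targeted-amplicon read simulation with a nanopore-like i.i.d. error model.
#
# Amplicon model: on-target reads are whole fragments between consecutive
# Cas9 cut sites on the sampled haplotype (the protocol amplifies and
# sequences entire cut fragments). Background reads ("blocking leakage") are
# uniform random haplotype fragments with log-normal length. Per-base edits
# are recorded per read so truth alignments can carry exact CIGARs.

# draw an edit profile for a fragment of length L:
#  base_ops: "M" kept, "X" substituted, "D" dropped; ins: insertions after base
.draw_edits <- function(L, rates) {
  u <- stats::runif(L)
  base_ops <- rep("M", L)
  base_ops[u < rates[1] + rates[2]] <- "X"
  base_ops[u < rates[2]] <- "D"   # del takes precedence below the del rate
  ins <- stats::rbinom(L, 1L, rates[3])
  list(base_ops = base_ops, ins = ins)
}

# realize the read sequence from a fragment and its edit profile
.apply_edits <- function(fragseq, base_ops, ins) {
  chars <- strsplit(fragseq, "")[[1]]
  xi <- which(base_ops == "X")
  if (length(xi))
    chars[xi] <- vapply(chars[xi], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  keep <- base_ops != "D"
  counts <- as.integer(keep) + ins
  total <- sum(counts)
  if (total == 0L) return("")
  out <- character(total)
  endpos <- cumsum(counts)
  basepos <- endpos - ins
  out[basepos[keep]] <- chars[keep]
  filled <- logical(total); filled[basepos[keep]] <- TRUE
  if (any(!filled))
    out[!filled] <- sample(c("A", "C", "G", "T"), sum(!filled), replace = TRUE)
  paste(out, collapse = "")
}

#' Simulate Cas9-targeted amplicon reads
#'
#' @param haplotypes A `"sample_haplotypes"` object from
#'   [apply_svs_to_reference()].
#' @param cut_sites data.frame of designed cuts with columns `chrom`, `cut`
#'   (0-based inter-base reference coordinate; NA for element guides),
#'   `sv_id`, `role` and optionally `consensus_offset` (element guides,
#'   offset of the cut within the inserted element).
#' @param config A [pipeline_config()]; uses the `[simulate]` section.
#' @param seed Integer seed; the same seed reproduces the read set bitwise.
#' @return List of class `"read_set"`: `reads` (data.frame `read_id`, `seq`,
#'   `qual`), `truth` (per-read list: haplotype, fragment interval, strand,
#'   category, sv_ids, edit profile), `seed`.
#' @export
simulate_reads <- function(haplotypes, cut_sites, config = pipeline_config(),
                           seed) {
  stopifnot(inherits(haplotypes, "sample_haplotypes"))
  if (missing(seed) || is.null(seed)) stop("simulate_reads requires a seed")
  scfg <- config$simulate
  rates <- c(sub = scfg$error_sub, del = scfg$error_del, ins = scfg$error_ins)
  if (any(rates < 0) || any(rates > 0.2)) stop("error rates must lie in [0, 0.2]")
  if (scfg$on_target_fraction <= 0 || scfg$on_target_fraction > 1)
    stop("on_target_fraction must lie in (0, 1]")
  set.seed(as.integer(seed))

  # lift designed cuts onto each haplotype
  frag_tbl <- list()
  for (h in 1:2) {
    maps <- if (h == 1L) haplotypes$map1 else haplotypes$map2
    for (ch in unique(cut_sites$chrom[!is.na(cut_sites$cut)])) {
      rows <- cut_sites[!is.na(cut_sites$cut) & cut_sites$chrom == ch, , drop = FALSE]
      if (!ch %in% names(maps)) next
      pos <- vapply(rows$cut, function(c) .lift_cut(maps[[ch]], c), numeric(1))
      labs <- rows$sv_id
      # element-guide cuts live inside inserted blocks
      el <- cut_sites[is.na(cut_sites$cut), , drop = FALSE]
      if (nrow(el)) for (k in seq_len(nrow(el))) {
        blk <- maps[[ch]][is.na(maps[[ch]]$ref_start) &
                          maps[[ch]]$label == el$sv_id[k], , drop = FALSE]
        if (nrow(blk)) {
          pos <- c(pos, blk$hap_start[1] + el$consensus_offset[k])
          labs <- c(labs, el$sv_id[k])
        }
      }
      keep <- !is.na(pos)
      pos <- pos[keep]; labs <- labs[keep]
      o <- order(pos); pos <- pos[o]; labs <- labs[o]
      dup <- duplicated(pos); pos <- pos[!dup]; labs <- labs[!dup]
      if (length(pos) < 2L) next
      for (i in seq_len(length(pos) - 1L)) {
        len <- pos[i + 1L] - pos[i]
        if (len >= scfg$amp_min && len <= scfg$amp_max)
          frag_tbl[[length(frag_tbl) + 1L]] <- list(
            hap = h, chrom = ch, start = pos[i], end = pos[i + 1L],
            sv_ids = unique(c(labs[i], labs[i + 1L])))
      }
    }
  }
  if (length(frag_tbl) == 0L) stop("no amplifiable fragments between cut sites")

  w <- scfg$allele_weights / mean(scfg$allele_weights)
  reads <- list(); truth <- list()
  emit <- function(hapseqs, hap, ch, a, b, category, sv_ids) {
    L <- b - a
    if (scfg$length_jitter > 0) {
      trim <- round(L * stats::runif(1, 0, scfg$length_jitter))
      b <- b - trim; L <- b - a
      if (L < 50) return(invisible(NULL))
    }
    fragseq <- .subseq0(hapseqs[[ch]], a, b)
    ed <- .draw_edits(L, c(rates["sub"], rates["del"], rates["ins"]))
    seq_f <- .apply_edits(fragseq, ed$base_ops, ed$ins)
    if (nchar(seq_f) == 0L) return(invisible(NULL))
    strand <- sample(c("+", "-"), 1L)
    rid <- sprintf("read%05d", length(reads) + 1L)
    reads[[length(reads) + 1L]] <<- data.frame(
      read_id = rid,
      seq = if (strand == "+") seq_f else reverse_complement(seq_f),
      qual = strrep("I", nchar(seq_f)), stringsAsFactors = FALSE)
    truth[[rid]] <<- list(read_id = rid, category = category, hap = hap,
                          chrom = ch, frag_start = a, frag_end = b,
                          strand = strand, sv_ids = sv_ids,
                          base_ops = ed$base_ops, ins = ed$ins,
                          n_edits = sum(ed$base_ops != "M") + sum(ed$ins))
    invisible(NULL)
  }

  for (fr in frag_tbl) {
    hapseqs <- if (fr$hap == 1L) haplotypes$hap1 else haplotypes$hap2
    n <- round(scfg$n_reads_per_target * w[fr$hap])
    for (k in seq_len(n))
      emit(hapseqs, fr$hap, fr$chrom, fr$start, fr$end, "target", fr$sv_ids)
  }
  n_target <- length(reads)
  n_bg <- round(n_target * (1 - scfg$on_target_fraction) / scfg$on_target_fraction)
  if (n_bg > 0) {
    chroms <- names(haplotypes$ref)
    clen1 <- vapply(haplotypes$hap1, nchar, numeric(1))
    clen2 <- vapply(haplotypes$hap2, nchar, numeric(1))
    for (k in seq_len(n_bg)) {
      h <- sample(1:2, 1L)
      clen <- if (h == 1L) clen1 else clen2
      ch <- if (length(chroms) == 1L) chroms else
        sample(chroms, 1L, prob = clen / sum(clen))
      L <- max(200, round(stats::rlnorm(1, log(scfg$background_median),
                                        scfg$background_sdlog)))
      L <- min(L, clen[[ch]] - 1)
      a <- sample.int(clen[[ch]] - L, 1L) - 1L
      emit(if (h == 1L) haplotypes$hap1 else haplotypes$hap2,
           h, ch, a, a + L, "background", character(0))
    }
  }
  structure(list(reads = do.call(rbind, reads), truth = truth,
                 seed = as.integer(seed)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cats <- table(vapply(x$truth, `[[`, character(1), "category"))
  cat(sprintf("<read_set> %d reads (seed %d): %s\n", nrow(x$reads), x$seed,
              paste(sprintf("%s=%d", names(cats), cats), collapse = ", ")))
  invisible(x)
}

#' Write a read set as FASTQ (Phred+33, constant quality stub)
#' @param read_set A `read_set`.
#' @param path Output path.
#' @export
write_fastq <- function(read_set, path) {
  r <- read_set$reads
  lines <- as.vector(rbind(paste0("@", r$read_id), r$seq, "+", r$qual))
  writeLines(lines, path)
  invisible(path)
}
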