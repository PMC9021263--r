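# Sequence primitives. Sequences travel through the package as named
# character vectors over {A,C,G,T,N}; Biostrings handles file I/O and
# reverse complementation.

.normalize_seq <- function(s, name) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) {
    # non-ACGTN IUPAC ambiguity codes degrade to N; anything else is an error
    bad <- gsub("[ACGTNRYSWKMBDHV]", "", s)
    if (nzchar(bad))
      stop("illegal character(s) '", substr(bad, 1, 10), "' in sequence '", name, "'")
    n_amb <- nchar(gsub("[ACGTN]", "", s))
    warning(n_amb, " ambiguous IUPAC base(s) converted to N in '", name, "'")
    s <- gsub("[RYSWKMBDHV]", "N", s)
  }
  s
}

#' Load a FASTA file as a named vector of normalized sequences
#'
#' Records are uppercased; lowercase (soft-masked) bases are kept as their
#' uppercase calls; IUPAC ambiguity codes other than ACGTN become N with a
#' warning. Multi-line and CRLF dialects are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record, alphabet
#'   restricted to A, C, G, T, N.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", paste(nm[nchar(seqs) == 0L], collapse = ", "))
  out <- vapply(seq_along(seqs), function(i) .normalize_seq(seqs[[i]], nm[[i]]),
                character(1))
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' Output is LF-terminated and wrapped at `width` columns;
#' `load_fasta(write_fasta(x, f))` recovers `x` exactly.
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Involution over the {A,C,G,T,N} alphabet; N maps to N. Vectorized.
#'
#' @param seq Character vector of sequences over A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGN")  # "NCTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq)))
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Generate a seeded random genome
#'
#' Uniform i.i.d. bases; used for toy references and simulation fixtures.
#'
#' @param lengths Named integer vector: sequence name -> length.
#' @param seed Integer seed.
#' @param gc GC fraction (default 0.5).
#' @return Named character vector of sequences.
#' @export
random_genome <- function(lengths, seed, gc = 0.5) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(out) <- names(lengths)
  out
}

# substring by 0-based half-open interval
.subseq0 <- function(seq, start, end) substr(seq, start + 1, end)
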