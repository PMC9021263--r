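# Independent oracles and shared fixtures for the suite. Everything is
# generated in code; nothing is read from disk.

# --- independent quadratic DP oracle for local alignment (Gotoh, affine;
# gap of length L costs open + L*ext) -----------------------------------
sw_oracle <- function(a, b, match = 2, mismatch = -4, open = 4, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    sc <- if (A[i - 1] == B[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# --- brute-force both-strand protospacer scan (vectorized position walk) --
brute_protospacers <- function(s, w0 = 0) {
  n <- nchar(s)
  if (n < 23) return(data.frame(strand = character(), cut = integer()))
  i <- seq_len(n - 22)
  w23 <- substring(s, i, i + 22)
  fwd <- substring(w23, 22, 23) == "GG" & !grepl("N", substring(w23, 1, 21))
  rev <- substring(w23, 1, 2) == "CC" & !grepl("N", substring(w23, 3, 23))
  rbind(
    data.frame(strand = "+", cut = w0 + i[fwd] - 1 + 17),
    data.frame(strand = "-", cut = w0 + i[rev] - 1 + 6))
}

# --- constructed alignment-group fixtures -------------------------------
mk_segment <- function(read_id, chrom, pos1, strand, cigar, seq = NA_character_,
                       supplementary = FALSE) {
  castsv:::.segment_row(read_id, chrom, pos1, strand, cigar, supplementary,
                        NA_integer_, seq)
}

mk_groups <- function(segment_dfs, assigned_sv) {
  groups <- lapply(seq_along(segment_dfs), function(i) {
    g <- segment_dfs[[i]]
    list(read_id = g$read_id[1], segments = g, assigned_sv = assigned_sv,
         allele_class = NA_character_)
  })
  structure(list(groups = groups, n_unmapped = 0L),
            class = "alignment_groups")
}

mk_guide_set <- function(sv_id, sv_type, roles, cuts, chrom,
                         consensus_offset = NA_real_) {
  g <- data.frame(role = roles, chrom = chrom, cut = cuts, strand = "+",
                  spacer = strrep("A", 20), pam = "AGG",
                  start = ifelse(is.na(cuts), NA, cuts - 17),
                  end = ifelse(is.na(cuts), NA, cuts + 3),
                  uniqueness = 1,
                  consensus_offset = consensus_offset,
                  stringsAsFactors = FALSE)
  structure(list(sv_id = sv_id, sv_type = sv_type, guides = g,
                 element_name = NA_character_, notes = ""),
            class = "guide_set")
}

# --- cached whole-workflow runs on the bundled toy ----------------------
.fixture_env <- new.env(parent = emptyenv())

toy_run <- function(mode = c("zero", "default")) {
  mode <- match.arg(mode)
  key <- paste0("toy_", mode)
  if (is.null(.fixture_env[[key]])) {
    toy <- toy_genome(42)
    cfg <- if (mode == "zero")
      pipeline_config(simulate = list(error_sub = 0, error_ins = 0,
                                      error_del = 0))
    else pipeline_config()
    res <- run_typing_workflow(toy$ref, toy$catalog, toy$applied, toy$element,
                               cfg, seed = 7,
                               outdir = file.path(tempdir(), key))
    .fixture_env[[key]] <- list(toy = toy, cfg = cfg, res = res)
  }
  .fixture_env[[key]]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
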