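mini_haps <- function(seed = 55) {
  ref <- random_genome(c(c1 = 30000L), seed)
  svs <- list(
    applied_sv("d", "deletion", "c1", 12000, 14500, zygosity = "het"),
    applied_sv("i", "insertion", "c1", 20000, 20000,
               inserted_seq = random_genome(c(e = 800L), seed + 1)[[1]],
               zygosity = "hom"),
    applied_sv("v", "inversion", "c1", 24000, 27000, zygosity = "hom"))
  list(ref = ref, svs = svs, haps = apply_svs_to_reference(ref, svs))
}

test_that("haplotype construction edits sequences and keeps exact liftover", {
  m <- mini_haps()
  h <- m$haps
  ref <- m$ref[["c1"]]
  # het deletion: haplotype 1 untouched, haplotype 2 shorter by the interval
  expect_identical(substr(h$hap1[["c1"]], 1, 12000), substr(ref, 1, 12000))
  expect_equal(nchar(h$hap2[["c1"]]), 30000 - 2500 + 800)
  expect_identical(substr(h$hap2[["c1"]], 11990, 12010),
                   paste0(substr(ref, 11990, 12000), substr(ref, 14501, 14510)))
  # hom inversion: both haplotypes carry the reverse-complemented block
  inv_ref <- reverse_complement(substr(ref, 24001, 27000))
  expect_identical(substr(h$hap1[["c1"]], 24001 + 800, 27000 + 800), inv_ref)
  # liftover round-trips outside edited bases
  for (cut in c(5000, 15000, 23000)) {
    hcut <- castsv:::.lift_cut(h$map1$c1, cut)
    blocks <- castsv:::.hap_to_ref_blocks(h$map1$c1, hcut - 10, hcut + 10)
    expect_equal(blocks$ref_start[1] + 10 - blocks$frag_start[1], cut)
  }
  # a cut inside the deleted region vanishes from haplotype 2
  expect_true(is.na(castsv:::.lift_cut(h$map2$c1, 13000)))
  expect_error(apply_svs_to_reference(m$ref, list(
    applied_sv("x", "deletion", "c1", 100, 500),
    applied_sv("y", "deletion", "c1", 400, 900))), "overlap")
})

test_that("breakpoints recovered by alignment-free string diff equal the truth", {
  m <- mini_haps()
  ref <- m$ref[["c1"]]; hap2 <- m$haps$hap2[["c1"]]
  # first divergence from the left locates the 5' deletion breakpoint
  i <- 1
  while (substr(ref, i, i) == substr(hap2, i, i)) i <- i + 1
  expect_equal(i - 1, m$svs[[1]]$truth_breakpoints[1])
})

test_that("simulation is seeded, honours the amplicon model and error rates", {
  m <- mini_haps()
  cuts <- data.frame(chrom = "c1",
                     cut = c(9000, 12500, 15500),
                     sv_id = "d", role = c("flank_5p", "internal", "flank_3p"),
                     consensus_offset = NA_real_)
  cfg0 <- pipeline_config(simulate = list(error_sub = 0, error_ins = 0,
                                          error_del = 0,
                                          on_target_fraction = 1))
  rs <- simulate_reads(m$haps, cuts, cfg0, seed = 3)
  # zero-noise identity: every read is an exact haplotype substring
  for (rid in rs$reads$read_id) {
    tr <- rs$truth[[rid]]
    hapseq <- (if (tr$hap == 1) m$haps$hap1 else m$haps$hap2)[[tr$chrom]]
    frag <- substr(hapseq, tr$frag_start + 1, tr$frag_end)
    row <- rs$reads[rs$reads$read_id == rid, ]
    got <- if (tr$strand == "+") row$seq else reverse_complement(row$seq)
    expect_identical(got, frag)
  }
  # determinism: same seed -> byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(simulate_reads(m$haps, cuts, cfg0, seed = 3), f1)
  write_fastq(simulate_reads(m$haps, cuts, cfg0, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  # substitution-rate counting oracle: no indels, sub rate 0.05
  cfg5 <- pipeline_config(simulate = list(error_sub = 0.05, error_ins = 0,
                                          error_del = 0,
                                          on_target_fraction = 1,
                                          n_reads_per_target = 60))
  rs5 <- simulate_reads(m$haps, cuts, cfg5, seed = 4)
  mm <- 0; tot <- 0
  for (rid in rs5$reads$read_id) {
    tr <- rs5$truth[[rid]]
    hapseq <- (if (tr$hap == 1) m$haps$hap1 else m$haps$hap2)[[tr$chrom]]
    frag <- substr(hapseq, tr$frag_start + 1, tr$frag_end)
    row <- rs5$reads[rs5$reads$read_id == rid, ]
    got <- if (tr$strand == "+") row$seq else reverse_complement(row$seq)
    a <- strsplit(frag, "")[[1]]; b <- strsplit(got, "")[[1]]
    mm <- mm + sum(a != b); tot <- tot + length(a)
  }
  expect_gt(tot, 4e5)
  expect_lt(abs(mm / tot - 0.05), 0.005)
  # on-target fraction converges at the configured value
  cfg7 <- pipeline_config(simulate = list(n_reads_per_target = 350))
  rs7 <- simulate_reads(m$haps, cuts, cfg7, seed = 5)
  cats <- vapply(rs7$truth, `[[`, "", "category")
  expect_gt(length(cats), 1000)
  expect_lt(abs(mean(cats == "target") - 0.7), 0.03)
  expect_error(simulate_reads(m$haps, cuts[0, ], cfg0, seed = 1), "no amplifiable")
  expect_error(simulate_reads(m$haps, cuts, cfg0), "seed")
})

test_that("truth alignments carry exact CIGARs, clips, SA links and NM", {
  m <- mini_haps()
  # deletion below the split threshold -> single record with a D op
  cuts <- data.frame(chrom = "c1", cut = c(11000, 15500), sv_id = "d",
                     role = c("flank_5p", "flank_3p"),
                     consensus_offset = NA_real_)
  cfg0 <- pipeline_config(simulate = list(error_sub = 0, error_ins = 0,
                                          error_del = 0, on_target_fraction = 1,
                                          n_reads_per_target = 4))
  rs <- simulate_reads(m$haps, cuts, cfg0, seed = 9)
  sam <- tempfile(fileext = ".sam")
  emit_truth_alignments(rs, m$haps, sam, split_threshold = 10000)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t")
  cigars <- vapply(fields, `[[`, "", 6)
  # haplotype-2 deletion-spanning reads: aM dD bM with a+b = read length
  del_recs <- grep("^[0-9]+M2500D[0-9]+M$", cigars)
  expect_gt(length(del_recs), 0)
  for (i in del_recs) {
    mm <- as.numeric(strsplit(cigars[i], "[MD]")[[1]])
    expect_equal(mm[1] + mm[3], nchar(fields[[i]][10]))
    expect_equal(mm[1] + mm[3], 15500 - 11000 - 2500)
  }
  # haplotype-1 reads across the same window are contiguous
  expect_gt(sum(grepl("^4500M$", cigars)), 0)
  # format round-trip through Rsamtools
  g <- load_alignments(sam, "sam_bam")
  expect_equal(length(g$groups), nrow(rs$reads))

  # insertion reads: kM sS with k = cut-to-breakpoint distance
  cuts_i <- data.frame(chrom = "c1", cut = c(19400, NA), sv_id = "i",
                       role = c("flank_5p", "element"),
                       consensus_offset = c(NA, 600))
  rs_i <- simulate_reads(m$haps, cuts_i, cfg0, seed = 10)
  sam_i <- tempfile(fileext = ".sam")
  emit_truth_alignments(rs_i, m$haps, sam_i)
  body_i <- readLines(sam_i); body_i <- body_i[!startsWith(body_i, "@")]
  cig_i <- vapply(strsplit(body_i, "\t"), `[[`, "", 6)
  expect_true(all(grepl("^600M600S$", cig_i)))

  # NM equals the simulated edit count for single-record reads
  cfg_e <- pipeline_config(simulate = list(on_target_fraction = 1,
                                           n_reads_per_target = 6))
  rs_e <- simulate_reads(m$haps, cuts, cfg_e, seed = 11)
  sam_e <- tempfile(fileext = ".sam")
  emit_truth_alignments(rs_e, m$haps, sam_e)
  be <- readLines(sam_e); be <- be[!startsWith(be, "@")]
  fe <- strsplit(be, "\t")
  by_read <- split(fe, vapply(fe, `[[`, "", 1))
  for (rid in names(by_read)) {
    nm_sum <- sum(vapply(by_read[[rid]], function(f) {
      as.integer(sub("NM:i:", "", grep("^NM:i:", f, value = TRUE)[1]))
    }, numeric(1)))
    expect_equal(nm_sum, rs_e$truth[[rid]]$n_edits, info = rid)
  }

  # inversion reads: two opposite-strand records linked by SA tags
  cuts_v <- data.frame(chrom = "c1", cut = c(22000, 26500), sv_id = "v",
                       role = c("flank_5p", "internal"),
                       consensus_offset = NA_real_)
  rs_v <- simulate_reads(m$haps, cuts_v, cfg0, seed = 12)
  sam_v <- tempfile(fileext = ".sam")
  emit_truth_alignments(rs_v, m$haps, sam_v)
  gv <- load_alignments(sam_v, "sam_bam")
  two_strand <- vapply(gv$groups, function(g)
    nrow(g$segments) == 2 && length(unique(g$segments$strand)) == 2, logical(1))
  expect_gt(mean(two_strand), 0)
  raw_v <- readLines(sam_v); raw_v <- raw_v[!startsWith(raw_v, "@")]
  expect_true(any(grepl("SA:Z:", raw_v)))
})
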