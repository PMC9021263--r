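# Alignment-driven breakpoint calling: constructed fixtures exercise the
# boundary-extraction conventions; simulated sets exercise recovery.

test_that("SAM loading groups primary and SA-linked supplementary records", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:10000",
    paste("r1", 0, "c1", 101, 60, "100M200S", "*", 0, 0, strrep("A", 300),
          strrep("I", 300), "NM:i:0", "SA:Z:c1,2001,+,100S200M,60,0;",
          sep = "\t"),
    paste("r1", 2048, "c1", 2001, 60, "100S200M", "*", 0, 0, strrep("A", 300),
          strrep("I", 300), "NM:i:0", "SA:Z:c1,101,+,100M200S,60,0;",
          sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII", sep = "\t")),
    sam)
  g <- load_alignments(sam, "sam_bam")
  expect_equal(length(g$groups), 1L)
  expect_equal(g$n_unmapped, 1L)
  seg <- g$groups[[1]]$segments
  expect_equal(nrow(seg), 2L)
  expect_equal(sum(seg$is_supplementary), 1L)
  expect_equal(seg$ref_start, c(100, 2000))
  expect_equal(seg$read_start, c(0, 100))    # read-coordinate order
  expect_equal(seg$left_clip, c(0, 100))
})

test_that("PAF requires a CIGAR tag and reproduces SAM-equivalent geometry", {
  paf <- tempfile(fileext = ".paf")
  writeLines(paste("r1", 300, 0, 300, "+", "c1", 10000, 100, 400, 300, 300, 60,
                   sep = "\t"), paf)
  expect_error(load_alignments(paf, "paf"), "cg")
  writeLines(paste("r1", 300, 50, 300, "+", "c1", 10000, 100, 350, 250, 250,
                   60, "cg:Z:250M", sep = "\t"), paf)
  g <- load_alignments(paf, "paf")
  seg <- g$groups[[1]]$segments
  expect_equal(seg$ref_start, 100)
  expect_equal(seg$ref_end, 350)
  expect_equal(seg$left_clip, 50)
  expect_equal(seg$read_start, 50)
})

test_that("reads are assigned to the target whose cut site they abut", {
  gs <- mk_guide_set("svA", "deletion", c("flank_5p", "internal", "flank_3p"),
                     c(1000, 4500, 12000), "c1")
  seg_on <- mk_segment("r1", "c1", 1001, "+", "3500M")   # starts at cut 1000
  seg_off <- mk_segment("r2", "c1", 1151, "+", "3500M")  # 150 bp from any cut
  groups <- mk_groups(list(seg_on, seg_off), NA_character_)
  out <- assign_reads_to_targets(groups, list(gs), tol = 100)
  expect_equal(out$groups[[1]]$assigned_sv, "svA")
  expect_equal(out$groups[[2]]$assigned_sv, "background")
})

test_that("deletion calling extracts junctions from split and CIGAR-D evidence", {
  cfg <- pipeline_config()
  # geometry echoing the published het deletion: reads start at the shared
  # 5' cut, 5' segments end at 45,509,371, 3' segments resume downstream
  cutA <- 45507951; cutB <- 45511479; cutC <- 45518936
  gs <- mk_guide_set("del_fig", "deletion",
                     c("flank_5p", "internal", "flank_3p"),
                     c(cutA, cutB, cutC), "chr12")
  sv <- sv_record("del_fig", gi("chr12", 45504426, 45517614), "deletion")
  alt_reads <- lapply(1:5, function(i) {
    rbind(
      mk_segment(paste0("a", i), "chr12", cutA + 1, "+",
                 "1420M4123S"),                        # ends at 45,509,371
      mk_segment(paste0("a", i), "chr12", 45514814, "+",
                 "1420S4123M", supplementary = TRUE))
  })
  ref_reads <- lapply(1:6, function(i)
    mk_segment(paste0("r", i), "chr12", cutA + 1, "+", "3528M"))
  groups <- mk_groups(c(alt_reads, ref_reads), "del_fig")
  call <- call_deletion(groups, sv, gs, cfg)
  expect_equal(call$breakpoints$pos[call$breakpoints$side == "5p"], 45509371)
  expect_equal(call$breakpoints$pos[call$breakpoints$side == "3p"], 45514814)
  expect_equal(call$genotype, "het")
  expect_equal(unname(call$support), c(6L, 5L))
  expect_equal(call$sv_length, 45514814 - 45509371 - 1)
  # the same junctions via a within-segment D op
  one_rec <- lapply(1:4, function(i)
    mk_segment(paste0("d", i), "chr12", cutA + 1, "+",
               "1420M5442D4123M"))
  call2 <- call_deletion(mk_groups(one_rec, "del_fig"), sv, gs, cfg)
  expect_equal(call2$breakpoints$pos, c(45509371, 45514814))
  # no assigned reads -> no_call
  expect_equal(call_deletion(mk_groups(list(), "x"), sv, gs, cfg)$genotype,
               "no_call")
})

test_that("an unaligned wedge at the junction downgrades the resumption side", {
  cfg <- pipeline_config()
  cutA <- 1000; cutB <- 4500; cutC <- 15000
  gs <- mk_guide_set("dN", "deletion", c("flank_5p", "internal", "flank_3p"),
                     c(cutA, cutB, cutC), "c1")
  sv <- sv_record("dN", gi("c1", 1500, 12000), "deletion")
  # 500 read bases between the aligned spans are clipped in both records
  reads <- lapply(1:4, function(i) rbind(
    mk_segment(paste0("w", i), "c1", cutA + 1, "+", "1000M2500S"),
    mk_segment(paste0("w", i), "c1", 12001, "+", "1500S2000M",
               supplementary = TRUE)))
  ref <- c(c1 = paste0(strrep("A", 5000), strrep("N", 50),
                       strrep("A", 15000)))
  call <- call_deletion(mk_groups(reads, "dN"), sv, gs, cfg, reference = ref)
  expect_equal(call$breakpoints$pos, c(2000, 12001))
  expect_equal(call$breakpoints$confidence, c("high", "low"))
  expect_true("reference_N_gap" %in% call$flags)
  expect_true(is.na(call$sv_length))
})

test_that("insertion calling recovers the clip junction and confirms the element", {
  cfg <- pipeline_config()
  set.seed(71)
  element <- c(L1 = random_seq(6000))
  tail_seq <- substr(element[["L1"]], 1, 800)
  gs <- mk_guide_set("ins_fig", "insertion", c("flank_5p", "element"),
                     c(33863402, NA), "chr12", consensus_offset = c(NA, 800))
  sv <- sv_record("ins_fig", gi("chr12", 33864300, 33864500), "insertion",
                  size_estimate = 6000, zygosity = "hom")
  # clips begin right after reported base 33,864,403
  reads <- lapply(1:5, function(i)
    mk_segment(paste0("i", i), "chr12", 33863403, "+", "1001M800S",
               seq = paste0(random_seq(1001), tail_seq)))
  call <- call_insertion(mk_groups(reads, "ins_fig"), sv, gs, element, cfg)
  expect_equal(call$breakpoints$pos, 33864403)
  expect_equal(call$genotype, "hom_alt")
  expect_true("element_confirmed" %in% call$flags)
  expect_equal(call$inserted_consensus, tail_seq)
  # random tails are not element-confirmed (negative control)
  reads_neg <- lapply(1:5, function(i)
    mk_segment(paste0("n", i), "chr12", 33863403, "+", "1001M800S",
               seq = paste0(random_seq(1001), random_seq(800))))
  call_neg <- call_insertion(mk_groups(reads_neg, "ins_fig"), sv, gs, element,
                             cfg)
  expect_false("element_confirmed" %in% call_neg$flags)
  # no clipped evidence -> no_call
  bare <- lapply(1:4, function(i)
    mk_segment(paste0("b", i), "chr12", 33863403, "+", "1001M"))
  expect_equal(call_insertion(mk_groups(bare, "ins_fig"), sv, gs, element,
                              cfg)$genotype, "no_call")
})

test_that("inversion calling reports both junctions from opposite-strand pairs", {
  cfg <- pipeline_config()
  # canonical geometry carrying the published junctions 17,768,358 and
  # 17,861,570: flank cut 2,600 bp left of the inversion, internal cut
  # 3,900 bp left of its 3' end -> 6.5 kbp fragment
  start0 <- 17768358; end0 <- 17861570
  f <- start0 - 2600; p <- end0 - 3900
  gs <- mk_guide_set("inv_fig", "inversion", c("flank_5p", "internal"),
                     c(f, p), "chr12")
  sv <- sv_record("inv_fig", gi("chr12", start0 + 1900, end0 - 1900),
                  "inversion", zygosity = "hom")
  reads <- lapply(1:6, function(i) rbind(
    mk_segment(paste0("v", i), "chr12", f + 1, "+", "2600M3900S"),
    mk_segment(paste0("v", i), "chr12", p + 1, "-", "3900M2600S",
               supplementary = TRUE)))
  call <- call_inversion(mk_groups(reads, "inv_fig"), sv, gs, cfg)
  expect_equal(call$breakpoints$pos, c(17768358, 17861570))
  expect_equal(call$genotype, "hom_alt")
  expect_equal(call$sv_length, end0 - start0)
  # no opposite-strand evidence -> no_call
  flat <- lapply(1:4, function(i)
    mk_segment(paste0("f", i), "chr12", f + 1, "+", "6500M"))
  expect_equal(call_inversion(mk_groups(flat, "inv_fig"), sv, gs,
                              cfg)$genotype, "no_call")
})

test_that("identical inverted repeats at both junctions raise the ambiguity flag", {
  cfg <- pipeline_config(call = list(rep_span = 2000, len_min = 200))
  set.seed(83)
  rep_unit <- random_seq(2500)
  left <- random_seq(5000); mid <- random_seq(20000); right <- random_seq(5000)
  # reference with an exact inverted repeat just inside each junction
  refseq <- paste0(left, rep_unit, mid, reverse_complement(rep_unit), right)
  ref <- c(c1 = refseq)
  start0 <- 5000
  end0 <- nchar(refseq) - 5000
  f <- start0 - 1500; p <- end0 - 2000
  gs <- mk_guide_set("invr", "inversion", c("flank_5p", "internal"),
                     c(f, p), "c1")
  sv <- sv_record("invr", gi("c1", start0, end0), "inversion")
  reads <- lapply(1:4, function(i) rbind(
    mk_segment(paste0("v", i), "c1", f + 1, "+", "1500M2000S"),
    mk_segment(paste0("v", i), "c1", p + 1, "-", "2000M1500S",
               supplementary = TRUE)))
  call <- call_inversion(mk_groups(reads, "invr"), sv, gs, cfg, reference = ref)
  expect_true("inverted_repeat_ambiguity" %in% call$flags)
  expect_true(all(call$breakpoints$confidence == "ambiguous"))
  # without the repeat the same geometry is unflagged
  ref2 <- c(c1 = paste0(left, rep_unit, mid, random_seq(2500), right))
  call2 <- call_inversion(mk_groups(reads, "invr"), sv, gs, cfg,
                          reference = ref2)
  expect_false("inverted_repeat_ambiguity" %in% call2$flags)
})

test_that("genotyping uses support thresholds without allele balance", {
  cfg <- pipeline_config()
  expect_equal(genotype_target(c(ref = 171, alt = 5), cfg), "het")
  expect_equal(genotype_target(c(ref = 0, alt = 12), cfg), "hom_alt")
  expect_equal(genotype_target(c(ref = 12, alt = 0), cfg), "hom_ref")
  expect_equal(genotype_target(c(ref = 2, alt = 2), cfg), "no_call")
})

test_that("custom reference splices the insert and lifts coordinates exactly", {
  ref <- c(c = "AAAATTTT")
  cr <- build_custom_reference(ref, "c", 2, "CC")
  expect_identical(cr$sequences[["c"]], "AACCAATTTT")
  # liftover round-trip for every base outside the inserted block
  for (b in c(0, 1, 3, 6)) {           # 0-based reference base positions
    hb <- b + if (b >= 2) 2 else 0     # insert of length 2 after base 2
    blocks <- castsv:::.hap_to_ref_blocks(cr$map, hb, hb + 1)
    expect_equal(blocks$ref_start[1], b)
  }
  expect_error(build_custom_reference(ref, "c", 99, "CC"), "out of range")
  # end-to-end: the toy insertion's alt fragments are contiguous on the
  # custom reference built from the call
  run <- toy_run("zero")
  call <- run$res$calls$ins1
  custom <- build_custom_reference(run$toy$ref, "ctg1",
                                   call$breakpoints$pos[1],
                                   call$inserted_consensus)
  tr <- Filter(function(t) t$category == "target" && "ins1" %in% t$sv_ids &&
                 t$frag_end - t$frag_start < 10000, run$res$read_set$truth)
  frag <- tr[[1]]
  hapseq <- run$res$haplotypes$hap1[[frag$chrom]]
  frag_seq <- substr(hapseq, frag$frag_start + 1, frag$frag_end)
  expect_true(grepl(substr(frag_seq, 1, nchar(frag_seq) - 20),
                    custom$sequences[["ctg1"]], fixed = TRUE))
})

test_that("coverage matches a brute-force per-base pileup", {
  segs <- list(
    mk_segment("r1", "c1", 101, "+", "1000M"),
    mk_segment("r2", "c1", 301, "+", "1000M"),
    mk_segment("r3", "c1", 901, "+", "500M"))
  groups <- mk_groups(segs, "t1")
  ti <- data.frame(sv_id = "t1", chrom = "c1", start = 100, end = 1400)
  cov <- compute_target_coverage(groups, ti)
  # brute force
  depth <- integer(1300)
  for (s in list(c(100, 1100), c(300, 1300), c(900, 1400)))
    depth[(s[1] - 100 + 1):(s[2] - 100)] <- depth[(s[1] - 100 + 1):(s[2] - 100)] + 1L
  expect_equal(cov$per_target$median, median(depth))
  expect_equal(cov$per_target$mean, mean(depth))
  # one 1 kbp target fully covered by 10 exact reads -> median 10
  ten <- mk_groups(lapply(1:10, function(i)
    mk_segment(paste0("x", i), "c1", 1, "+", "1000M")), "t2")
  cov10 <- compute_target_coverage(ten, data.frame(sv_id = "t2", chrom = "c1",
                                                   start = 0, end = 1000))
  expect_equal(cov10$per_target$median, 10)
  # no reads -> 0
  cov0 <- compute_target_coverage(mk_groups(list(), "z"),
                                  data.frame(sv_id = "z", chrom = "c9",
                                             start = 0, end = 500))
  expect_equal(cov0$per_target$median, 0)
})
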