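test_that("protospacer search matches SpCas9 geometry on constructed sites", {
  # single forward site: 20-mer spacer + AGG PAM, cut 3 nt 5' of the PAM
  ps <- find_protospacers(c(x = "ACGTACGTACGTACGTACGTAGG"), gi("x", 0, 23))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$strand, "+")
  expect_equal(ps$spacer, "ACGTACGTACGTACGTACGT")
  expect_equal(ps$pam, "AGG")
  expect_equal(ps$cut, 17)
  # no NGG / CCN at all
  expect_equal(nrow(find_protospacers(c(x = strrep("A", 100)), gi("x", 0, 100))),
               0L)
  # spacers containing N are excluded
  withN <- c(x = "ACGTACGTACNTACGTACGTAGG")
  expect_equal(nrow(find_protospacers(withN, gi("x", 0, 23))), 0L)
  expect_error(find_protospacers(c(x = "ACGT"), gi("x", 0, 4)), "23")
  expect_error(find_protospacers(c(x = strrep("A", 50)), gi("y", 0, 30)),
               "not in reference")
})

test_that("protospacer search equals the brute-force both-strand scan", {
  set.seed(77)
  for (k in 1:100) {
    s <- random_seq(2000)
    got <- find_protospacers(stats::setNames(s, "r"), gi("r", 0, 2000))
    want <- brute_protospacers(s)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$strand, got$cut), paste(want$strand, want$cut))
  }
})

test_that("emitted protospacers re-extract exactly from the reference", {
  set.seed(31)
  ref <- c(r = random_seq(3000))
  ps <- find_protospacers(ref, gi("r", 100, 2900))
  expect_gt(nrow(ps), 50)
  for (i in seq_len(nrow(ps))) {
    fwd <- substr(ref[["r"]], ps$start[i] + 1, ps$end[i] + 3)
    site <- if (ps$strand[i] == "+") fwd else {
      # minus-strand context: PAM precedes the spacer on the forward strand
      reverse_complement(substr(ref[["r"]], ps$start[i] - 2, ps$end[i]))
    }
    expect_identical(site, paste0(ps$spacer[i], ps$pam[i]))
  }
})

test_that("screening enforces GC, homopolymer and exact-match uniqueness", {
  cfg <- pipeline_config()
  base <- find_protospacers(c(x = "ACGTACGTACGTACGTACGTAGG"), gi("x", 0, 23))
  polyA <- base
  polyA$spacer <- strrep("A", 20)
  expect_equal(nrow(screen_guides(polyA, c(x = "ACGT"), cfg,
                                  check_uniqueness = FALSE)), 0L)
  # a guide inside a duplicated segment is rejected (uniqueness 2)
  set.seed(8)
  unit <- random_seq(1000)
  ref <- c(g = paste0(unit, random_seq(500), unit))
  cand <- find_protospacers(ref, gi("g", 0, 900))
  screened <- screen_guides(cand, ref, cfg)
  expect_equal(nrow(screened), 0L)
  # same guides are kept when the duplication is removed
  ref1 <- c(g = paste0(unit, random_seq(500)))
  cand1 <- find_protospacers(ref1, gi("g", 0, 900))
  screened1 <- screen_guides(cand1, ref1, cfg)
  expect_gt(nrow(screened1), 0L)
  expect_true(all(screened1$uniqueness == 1))
  gc <- vapply(screened1$spacer, function(s)
    nchar(gsub("[AT]", "", s)) / 20, numeric(1))
  expect_true(all(gc >= 0.25 & gc <= 0.75))
})

test_that("deletion design gives the shared-A two-pair layout with target spacing", {
  set.seed(12)
  ref <- c(t = random_seq(60000))
  sv <- sv_record("d1", gi("t", 25000, 38000), "deletion", zygosity = "het")
  cfg <- pipeline_config()
  gs <- design_deletion_guides(sv, ref, cfg)
  g <- gs$guides
  expect_setequal(g$role, c("flank_5p", "internal", "flank_3p"))
  a <- g$cut[g$role == "flank_5p"]; b <- g$cut[g$role == "internal"]
  c3 <- g$cut[g$role == "flank_3p"]
  expect_true(a < b && b < c3)
  expect_true(b > 25000 && b < 38000)       # internal cut inside the interval
  expect_true(c3 >= 38000)                  # 3' anchor beyond the interval
  expect_lt(abs((b - a) - 3500), 200)       # ref-allele fragment near target
  expect_lte(c3 - a, cfg$design$max_fragment)
  # predicted mutant fragment arithmetic: span minus deletion length
  fr <- predict_fragments(sv, gs, cfg)
  alt <- Filter(function(f) f$allele == "alt", fr)[[1]]
  expect_equal(alt$length, (c3 - a) - 13000)
  expect_equal(alt$signature, "gapped_two_segment")
  # a deletion longer than max_fragment is infeasible under PCR mode
  big <- sv_record("d2", gi("t", 10000, 45000), "deletion")
  expect_error(design_deletion_guides(big, ref, cfg), "max_fragment")
})

test_that("insertion design supports element and flank-only modes", {
  set.seed(13)
  ref <- c(t = random_seq(40000))
  el <- c(L1 = random_seq(6000))
  cfg <- pipeline_config()
  sv <- sv_record("i1", gi("t", 20000, 20200), "insertion",
                  size_estimate = 6000, zygosity = "hom")
  gs <- design_insertion_guides(sv, ref, el, cfg)
  expect_setequal(gs$guides$role, c("flank_5p", "element"))
  eg <- gs$guides[gs$guides$role == "element", ]
  expect_true(is.na(eg$cut))                 # no reference cut coordinate
  off <- eg$consensus_offset
  expect_true(off > 0 && off < 6000)
  # the recorded offset is a real cut of the consensus (brute-force check)
  bf <- brute_protospacers(el[["L1"]])
  expect_true(off %in% bf$cut)
  # flank-only: expected mutant fragment = reference span + inserted length
  sv2 <- sv_record("i2", gi("t", 20000, 20010), "insertion",
                   size_estimate = 5000)
  gs2 <- design_insertion_guides(sv2, ref, NULL, cfg)
  expect_setequal(gs2$guides$role, c("flank_5p", "flank_3p"))
  span <- diff(range(gs2$guides$cut))
  fr2 <- predict_fragments(sv2, gs2, cfg)
  alt2 <- Filter(function(f) f$allele == "alt", fr2)[[1]]
  expect_equal(alt2$length, span + 5000)
  expect_lt(abs(alt2$length - 7000), 2200)   # ~7 kbp with ~1 kbp margins
  # infeasible when the inserted length alone exceeds the PCR bound
  sv3 <- sv_record("i3", gi("t", 20000, 20010), "insertion",
                   size_estimate = 50000)
  expect_error(design_insertion_guides(sv3, ref, NULL, cfg), "infeasible")
  expect_error(design_insertion_guides(sv, ref, c(e = "ACGTACGT"), cfg),
               "23")
})

test_that("inversion design places flank + internal cuts hitting the fragment target", {
  set.seed(14)
  ref <- c(t = random_seq(150000))
  sv <- sv_record("v1", gi("t", 30000, 120000), "inversion", zygosity = "hom")
  cfg <- pipeline_config()
  gs <- design_inversion_guides(sv, ref, cfg)
  f <- gs$guides$cut[gs$guides$role == "flank_5p"]
  p <- gs$guides$cut[gs$guides$role == "internal"]
  expect_true(f < 30000)
  expect_true(p >= 115000 && p < 120000)     # within 5 kbp of the 3' end
  frag <- (30000 - f) + (120000 - p)
  expect_lt(abs(frag - 6500), 100)
  # no PAM sites in the internal window -> explicit error
  ref2 <- ref
  ref2[["t"]] <- paste0(substr(ref2[["t"]], 1, 114970), strrep("A", 5030),
                        substr(ref2[["t"]], 120001, 150000))
  expect_error(design_inversion_guides(sv, ref2, cfg), "internal window")
})

test_that("synthesis oligos follow the 55-mer template and shared scaffold", {
  o <- emit_synthesis_oligos(strrep("G", 20))
  expect_identical(o$template_oligo,
                   paste0("TTCTAATACGACTCACTATAG", strrep("G", 20),
                          "GTTTTAGAGCTAGA"))
  expect_equal(nchar(o$template_oligo), 55L)
  expect_error(emit_synthesis_oligos(strrep("G", 19)), "20 nt")
  # scaffold tail is the reverse complement of the overlap
  tail14 <- substr(o$scaffold_oligo, nchar(o$scaffold_oligo) - 13,
                   nchar(o$scaffold_oligo))
  expect_identical(tail14, reverse_complement("GTTTTAGAGCTAGA"))
  # one scaffold shared by all guides
  o2 <- emit_synthesis_oligos(strrep("C", 20))
  expect_identical(o$scaffold_oligo, o2$scaffold_oligo)
})
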