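# Pipeline orchestration: per-class guide design over a catalog, the
# bundled toy genome, and the subcommand driver used by the CLI script.

#' Design guide sets for every SV in a catalog
#'
#' Dispatches to the class-specific designers. Insertions use the element
#' consensus when provided (element mode), flank-only mode otherwise.
#' Records whose design is infeasible under the current configuration are
#' collected, not fatal.
#'
#' @param catalog An [sv_catalog()].
#' @param reference Named character vector.
#' @param element_consensus Optional named character sequence for insertions.
#' @param config A [pipeline_config()].
#' @return List with `guide_sets` and `failures` (data.frame sv_id, reason).
#' @export
design_catalog <- function(catalog, reference, element_consensus = NULL,
                           config = pipeline_config()) {
  gsets <- list(); fails <- list()
  for (r in catalog$records) {
    res <- tryCatch(
      switch(r$sv_type,
             deletion = design_deletion_guides(r, reference, config),
             insertion = design_insertion_guides(r, reference,
                                                 element_consensus, config),
             inversion = design_inversion_guides(r, reference, config),
             stop("no guide design for sv_type '", r$sv_type, "'")),
      error = function(e) e)
    if (inherits(res, "error"))
      fails[[length(fails) + 1L]] <- data.frame(sv_id = r$sv_id,
                                                reason = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    else gsets[[length(gsets) + 1L]] <- res
  }
  list(guide_sets = gsets,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(sv_id = character(), reason = character()))
}

#' Collect designed cut sites across guide sets
#'
#' @param guide_sets List of `guide_set` objects.
#' @return data.frame `chrom`, `cut` (0-based inter-base; NA for element
#'   guides), `sv_id`, `role`, `consensus_offset` — the input the simulator
#'   and target assignment expect.
#' @export
guide_cut_table <- function(guide_sets) {
  do.call(rbind, lapply(guide_sets, function(gs) {
    g <- gs$guides
    data.frame(chrom = g$chrom, cut = g$cut, sv_id = gs$sv_id, role = g$role,
               consensus_offset = g$consensus_offset, stringsAsFactors = FALSE)
  }))
}

#' The bundled toy study: 200-kbp reference with three known SVs
#'
#' One contig carrying a heterozygous 13.2-kbp deletion, a homozygous
#' 6-kbp mobile-element insertion (with a synthetic element consensus) and a
#' homozygous 30-kbp inversion — one SV per class the caller supports, at
#' sizes matching the targeted-assay regime. Everything is generated from
#' the seed; no data files ship with the package.
#'
#' @param seed Integer seed.
#' @return List with `ref`, `element` (consensus, named
#'   "L1_synthetic"), `catalog` ([sv_catalog()]), `applied` (list of
#'   [applied_sv()]), `truth` (data.frame sv_id, type, zygosity and 1-based
#'   truth breakpoints).
#' @export
toy_genome <- function(seed = 42) {
  ref <- random_genome(c(ctg1 = 200000L), seed)
  element <- random_genome(c(L1_synthetic = 6000L), seed + 1000L)
  ins_seq <- element[["L1_synthetic"]]
  applied <- list(
    applied_sv("del1", "deletion", "ctg1", 60000, 73200, zygosity = "het"),
    applied_sv("ins1", "insertion", "ctg1", 120000, 120000,
               inserted_seq = ins_seq, zygosity = "hom"),
    applied_sv("inv1", "inversion", "ctg1", 150000, 180000, zygosity = "hom"))
  catalog <- sv_catalog(list(
    sv_record("del1", gi("ctg1", 60000, 73200), "deletion", zygosity = "het"),
    # optical locus around the insertion point; inserted length estimated
    sv_record("ins1", gi("ctg1", 119900, 120100), "insertion",
              size_estimate = 6000, zygosity = "hom"),
    sv_record("inv1", gi("ctg1", 150000, 180000), "inversion",
              zygosity = "hom")), reference_name = "toy")
  truth <- do.call(rbind, lapply(applied, function(a)
    data.frame(sv_id = a$sv_id, sv_type = a$sv_type, zygosity = a$zygosity,
               breakpoints = I(list(a$truth_breakpoints)),
               stringsAsFactors = FALSE)))
  list(ref = ref, element = element, catalog = catalog, applied = applied,
       truth = truth)
}

#' Design-feasibility panel: candidate targets spanning 1-60 kbp
#'
#' A seeded 200-kbp random reference with SV records whose spans (or
#' inserted lengths) range from 1 to 60 kbp, used to exercise the PCR
#' feasibility bound: under PCR mode no accepted guide pair may predict a
#' fragment above `max_fragment`, and oversize targets must be rejected.
#'
#' @param seed Integer seed.
#' @return List with `ref` and `catalog`.
#' @export
feasibility_panel <- function(seed = 1) {
  ref <- random_genome(c(panel = 200000L), seed)
  mk <- function(id, type, start, span, size = NULL, zyg = "het") {
    sv_record(id, gi("panel", start, start + span), type, size, zyg)
  }
  recs <- list(
    mk("del_1k", "deletion", 8000, 1000),
    mk("del_2k", "deletion", 14000, 2000),
    mk("del_5k", "deletion", 22000, 5000),
    mk("del_12k", "deletion", 33000, 12000),
    mk("del_22k", "deletion", 51000, 22000),
    mk("del_60k", "deletion", 80000, 60000),      # exceeds the PCR bound
    # records may overlap: each is designed independently on the reference
    mk("inv_45k", "inversion", 85000, 45000, zyg = "hom"),
    mk("inv_9k", "inversion", 146000, 9000, zyg = "hom"),
    sv_record("ins_3k", gi("panel", 160000, 160100), "insertion", 3000),
    sv_record("ins_8k", gi("panel", 170000, 170100), "insertion", 8000),
    sv_record("ins_40k", gi("panel", 180000, 180100), "insertion", 40000))
  list(ref = ref, catalog = sv_catalog(recs, "feasibility"))
}

#' Predicted fragment lengths of accepted designs
#'
#' For each accepted guide set, the lengths of its amplifiable expected
#' fragments from [predict_fragments()], taking the upper bound for
#' deletion fragments whose true length is unknown pre-sequencing.
#'
#' @param catalog The designed [sv_catalog()].
#' @param guide_sets Accepted guide sets from [design_catalog()].
#' @param config A [pipeline_config()].
#' @return data.frame `sv_id`, `allele`, `length`.
#' @export
accepted_fragment_lengths <- function(catalog, guide_sets,
                                      config = pipeline_config()) {
  ids <- vapply(guide_sets, `[[`, character(1), "sv_id")
  out <- list()
  for (r in catalog$records) {
    i <- match(r$sv_id, ids)
    if (is.na(i)) next
    for (f in predict_fragments(r, guide_sets[[i]], config)) {
      if (!f$amplifiable) next
      out[[length(out) + 1L]] <- data.frame(
        sv_id = f$sv_id, allele = f$allele,
        length = max(f$length, f$length_max, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.call_one <- function(groups, sv, gs, element_consensus, config, reference) {
  switch(sv$sv_type,
         deletion = call_deletion(groups, sv, gs, config, reference),
         insertion = call_insertion(groups, sv, gs, element_consensus, config,
                                    reference),
         inversion = call_inversion(groups, sv, gs, config, reference),
         stop("no caller for sv_type '", sv$sv_type, "'"))
}

#' Run the full typing workflow on in-memory inputs
#'
#' design -> digest -> simulate -> truth alignments -> call, returning every
#' intermediate. This is the engine behind the `end2end` subcommand and the
#' recovery experiments.
#'
#' @param ref Named character vector reference.
#' @param catalog [sv_catalog()] of targets.
#' @param applied List of [applied_sv()] describing the sample truth.
#' @param element_consensus Optional element consensus for insertions.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the simulation.
#' @param outdir Optional directory for artifacts (FASTA/FASTQ/SAM/VCF/TSV).
#' @return List: `guide_sets`, `fragments`, `haplotypes`, `read_set`,
#'   `groups`, `calls`, `coverage`, `artifacts` (paths, when `outdir` given).
#' @export
run_typing_workflow <- function(ref, catalog, applied, element_consensus = NULL,
                                config = pipeline_config(), seed,
                                outdir = NULL) {
  des <- design_catalog(catalog, ref, element_consensus, config)
  if (length(des$guide_sets) == 0L) stop("no SV could be designed")
  gsets <- des$guide_sets
  ids <- vapply(gsets, `[[`, character(1), "sv_id")
  fragments <- list()
  for (r in catalog$records) {
    i <- match(r$sv_id, ids)
    if (is.na(i)) next
    fragments <- c(fragments, predict_fragments(r, gsets[[i]], config))
  }
  haps <- apply_svs_to_reference(ref, applied)
  cuts <- guide_cut_table(gsets)
  rs <- simulate_reads(haps, cuts, config, seed)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(if (is.null(outdir)) tempdir() else outdir, "truth.sam")
  emit_truth_alignments(rs, haps, sam,
                        split_threshold = config$simulate$split_threshold)
  groups <- load_alignments(sam, "sam_bam")
  groups <- assign_reads_to_targets(groups, gsets, tol = config$call$tol)
  calls <- list()
  for (r in catalog$records) {
    i <- match(r$sv_id, ids)
    if (is.na(i)) next
    calls[[r$sv_id]] <- .call_one(groups, r, gsets[[i]], element_consensus,
                                  config, ref)
  }
  # per-target coverage over the designed cut span of each SV
  ti <- do.call(rbind, lapply(gsets, function(gs) {
    g <- gs$guides[!is.na(gs$guides$cut), , drop = FALSE]
    data.frame(sv_id = gs$sv_id, chrom = g$chrom[1],
               start = min(g$cut), end = max(g$cut), stringsAsFactors = FALSE)
  }))
  ti <- ti[ti$end > ti$start, , drop = FALSE]
  coverage <- compute_target_coverage(groups, ti)
  artifacts <- list(truth_sam = sam)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    artifacts$haplotypes_fasta <- file.path(outdir, "haplotypes.fasta")
    hapseqs <- c(stats::setNames(haps$hap1, paste0(names(haps$hap1), "_hap1")),
                 stats::setNames(haps$hap2, paste0(names(haps$hap2), "_hap2")))
    write_fasta(hapseqs, artifacts$haplotypes_fasta)
    artifacts$reads_fastq <- file.path(outdir, "reads.fastq")
    write_fastq(rs, artifacts$reads_fastq)
    artifacts$guides_tsv <- file.path(outdir, "guide_panel.tsv")
    write_guide_panel(gsets, artifacts$guides_tsv)
    artifacts$fragments_tsv <- file.path(outdir, "expected_fragments.tsv")
    write_fragment_table(fragments, artifacts$fragments_tsv)
    artifacts$calls_vcf <- file.path(outdir, "calls.vcf")
    write_vcf(calls, ref, artifacts$calls_vcf)
    artifacts$report_tsv <- file.path(outdir, "report.tsv")
    write_report_tsv(calls, gsets, fragments, coverage, artifacts$report_tsv)
  }
  list(guide_sets = gsets, design_failures = des$failures,
       fragments = fragments, haplotypes = haps, read_set = rs,
       groups = groups, calls = calls, coverage = coverage,
       artifacts = artifacts)
}

#' Command-style pipeline driver
#'
#' Thin dispatcher over the package functions, mirroring the workflow
#' stages. Artifacts land in `outdir`; per-stage counters are logged to
#' stderr.
#'
#' @param subcommand One of "design", "digest", "simulate", "call",
#'   "report", "end2end".
#' @param config A `"castsv_config"` (or path to a YAML config).
#' @param inputs Named list of stage inputs: `reference` (FASTA path),
#'   `sv_table` + `dialect`, `element` (FASTA path), `alignments`
#'   (SAM/BAM/PAF path) as each stage requires; `seed` overrides the config
#'   seed.
#' @param outdir Output directory (default "castsv_out").
#' @return Invisible list of produced artifacts / results.
#' @export
run_pipeline <- function(subcommand = c("design", "digest", "simulate", "call",
                                        "report", "end2end"),
                         config = pipeline_config(), inputs = list(),
                         outdir = "castsv_out") {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- load_config(config)
  seed <- inputs$seed %||% config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[castsv] ", sprintf(...))

  if (subcommand == "end2end") {
    if (is.null(seed)) stop("end2end requires a seed")
    toy <- toy_genome(seed)
    res <- run_typing_workflow(toy$ref, toy$catalog, toy$applied, toy$element,
                               config, seed, outdir)
    n_bg <- sum(vapply(res$groups$groups, function(g)
      identical(g$assigned_sv, "background"), logical(1)))
    log_msg("end2end: %d reads, %d groups (%d background), %d call(s)",
            nrow(res$read_set$reads), length(res$groups$groups), n_bg,
            length(res$calls))
    for (cl in res$calls)
      log_msg("  %s: %s, breakpoints %s", cl$sv_id, cl$genotype,
              paste(cl$breakpoints$pos, collapse = "/"))
    return(invisible(res))
  }

  need <- function(key) {
    if (is.null(inputs[[key]])) stop("subcommand '", subcommand,
                                     "' requires input '", key, "'")
    inputs[[key]]
  }
  ref <- load_fasta(need("reference"))
  catalog <- parse_sv_table(need("sv_table"), inputs$dialect %||% "bed")
  element <- if (!is.null(inputs$element)) load_fasta(inputs$element) else NULL

  des <- design_catalog(catalog, ref, element, config)
  log_msg("design: %d/%d SV(s) designed", length(des$guide_sets),
          length(catalog))
  if (nrow(des$failures)) for (i in seq_len(nrow(des$failures)))
    log_msg("  failed %s: %s", des$failures$sv_id[i], des$failures$reason[i])
  gsets <- des$guide_sets
  ids <- vapply(gsets, `[[`, character(1), "sv_id")
  arts <- list()
  if (subcommand == "design") {
    arts$guides_tsv <- file.path(outdir, "guide_panel.tsv")
    write_guide_panel(gsets, arts$guides_tsv)
    return(invisible(c(arts, list(guide_sets = gsets, failures = des$failures))))
  }

  fragments <- list()
  for (r in catalog$records) {
    i <- match(r$sv_id, ids)
    if (!is.na(i))
      fragments <- c(fragments, predict_fragments(r, gsets[[i]], config))
  }
  if (subcommand == "digest") {
    arts$fragments_tsv <- file.path(outdir, "expected_fragments.tsv")
    write_fragment_table(fragments, arts$fragments_tsv)
    log_msg("digest: %d expected fragment(s)", length(fragments))
    return(invisible(c(arts, list(fragments = fragments))))
  }

  if (subcommand == "simulate") {
    if (is.null(seed)) stop("simulate requires a seed")
    applied <- lapply(catalog$records, function(r) {
      if (r$sv_type == "insertion") {
        if (is.null(element)) stop("simulate: insertions require an element FASTA")
        applied_sv(r$sv_id, "insertion", r$interval$chrom,
                   r$interval$start, r$interval$start,
                   inserted_seq = element[[1]],
                   zygosity = if (r$zygosity == "unknown") "het" else r$zygosity)
      } else {
        applied_sv(r$sv_id, r$sv_type, r$interval$chrom, r$interval$start,
                   r$interval$end,
                   zygosity = if (r$zygosity == "unknown") "het" else r$zygosity)
      }
    })
    haps <- apply_svs_to_reference(ref, applied)
    rs <- simulate_reads(haps, guide_cut_table(gsets), config, seed)
    arts$reads_fastq <- file.path(outdir, "reads.fastq")
    write_fastq(rs, arts$reads_fastq)
    arts$truth_sam <- file.path(outdir, "truth.sam")
    emit_truth_alignments(rs, haps, arts$truth_sam,
                          config$simulate$split_threshold)
    arts$haplotypes_fasta <- file.path(outdir, "haplotypes.fasta")
    write_fasta(c(stats::setNames(haps$hap1, paste0(names(haps$hap1), "_hap1")),
                  stats::setNames(haps$hap2, paste0(names(haps$hap2), "_hap2"))),
                arts$haplotypes_fasta)
    log_msg("simulate: %d read(s) -> %s", nrow(rs$reads), arts$reads_fastq)
    return(invisible(c(arts, list(read_set = rs, haplotypes = haps))))
  }

  # call / report
  aln_path <- need("alignments")
  dialect <- if (grepl("\\.paf$", aln_path, ignore.case = TRUE)) "paf" else "sam_bam"
  groups <- load_alignments(aln_path, dialect)
  groups <- assign_reads_to_targets(groups, gsets, tol = config$call$tol)
  n_bg <- sum(vapply(groups$groups, function(g)
    identical(g$assigned_sv, "background"), logical(1)))
  log_msg("call: %d group(s), %d background, %d unmapped dropped",
          length(groups$groups), n_bg, groups$n_unmapped)
  calls <- list()
  for (r in catalog$records) {
    i <- match(r$sv_id, ids)
    if (!is.na(i))
      calls[[r$sv_id]] <- .call_one(groups, r, gsets[[i]], element, config, ref)
  }
  ti <- do.call(rbind, lapply(gsets, function(gs) {
    g <- gs$guides[!is.na(gs$guides$cut), , drop = FALSE]
    data.frame(sv_id = gs$sv_id, chrom = g$chrom[1], start = min(g$cut),
               end = max(g$cut), stringsAsFactors = FALSE)
  }))
  ti <- ti[ti$end > ti$start, , drop = FALSE]
  coverage <- compute_target_coverage(groups, ti)
  arts$calls_vcf <- file.path(outdir, "calls.vcf")
  write_vcf(calls, ref, arts$calls_vcf)
  arts$report_tsv <- file.path(outdir, "report.tsv")
  write_report_tsv(calls, gsets, fragments, coverage, arts$report_tsv)
  for (cl in calls)
    log_msg("  %s: %s (ref=%d, alt=%d)", cl$sv_id, cl$genotype,
            cl$support[["ref"]], cl$support[["alt"]])
  invisible(c(arts, list(calls = calls, coverage = coverage,
                         guide_sets = gsets)))
}
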