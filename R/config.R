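# Pipeline configuration: one nested list with sections mirroring the
# pipeline stages. YAML on disk; unknown keys are rejected so typos fail
# loudly rather than silently falling back to defaults.

.config_defaults <- function() {
  list(
    design = list(
      gc_min = 0.25,            # spacer GC fraction bounds
      gc_max = 0.75,
      max_homopolymer = 5L,     # longest tolerated mononucleotide run in a spacer
      w_out = 5000,             # bp the anchor window extends outside the SV interval
      w_in = 4000,              # bp the 5' anchor may reach inside the optical interval
      ref_fragment_target = 3500,  # target reference-allele fragment (bp)
      inv_fragment_target = 6500,  # target inversion sample fragment (bp)
      internal_window = 5000,   # inversion internal guide: window from the 3' end
      pcr_mode = TRUE,          # enforce amplifiable fragment sizes
      min_fragment = 1000,      # bp, under PCR mode
      max_fragment = 30000      # bp, under PCR mode ("under 25-30 kbp")
    ),
    digest = list(),
    simulate = list(
      n_reads_per_target = 20L,
      error_sub = 0.03, error_ins = 0.02, error_del = 0.04,
      on_target_fraction = 0.7, # residual background after end-blocking = 30%
      background_median = 2000, # bp, log-normal background fragment length
      background_sdlog = 0.5,
      allele_weights = c(1, 1), # per-haplotype sampling weights
      length_jitter = 0,        # optional uniform amplicon length jitter (fraction)
      amp_min = 200,            # amplifiable fragment bounds for the amplicon model
      amp_max = 30000,
      split_threshold = 10000   # deleted span above which truth alignments split
    ),
    call = list(
      tol = 100,        # bp, boundary-to-cut-site distance for target assignment
      min_del = 1000,   # bp, minimum deletion evidence (CIGAR D or reference gap)
      adj_tol = 50,     # bp, read-coordinate adjacency of split segments
      min_support = 3L, # reads per allele class to count it present
      min_clip = 200,   # bp, minimum soft clip taken as insertion evidence
      clip_tol = 100,   # bp, clips beyond this near a junction downgrade confidence
      cons_min = 2L,    # minimum per-column coverage in the clipped-tail consensus
      id_min = 0.80,    # identity to confirm an element over >= len_min columns
      len_min = 200,    # bp
      n_run = 10L,      # reference N-run length that flags reference_N_gap
      rep_span = 5000,  # bp examined inward from inversion breakpoints
      rep_id = 0.90     # identity flagging inverted-repeat ambiguity
    ),
    report = list(),
    seed = NULL
  )
}

.merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) in [", section, "]: ", paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Build a validated pipeline configuration
#'
#' Any subset of keys may be overridden; everything else keeps its
#' documented default. Unknown keys are rejected.
#'
#' @param design,digest,simulate,call,report Named lists of overrides.
#' @param seed Integer seed for every stochastic stage (required by
#'   simulation).
#' @return A list of class `"castsv_config"`.
#' @export
pipeline_config <- function(design = list(), digest = list(), simulate = list(),
                            call = list(), report = list(), seed = NULL) {
  d <- .config_defaults()
  cfg <- list(
    design = .merge_section(d$design, design, "design"),
    digest = .merge_section(d$digest, digest, "digest"),
    simulate = .merge_section(d$simulate, simulate, "simulate"),
    call = .merge_section(d$call, call, "call"),
    report = .merge_section(d$report, report, "report"),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  with(cfg$design, {
    if (gc_min < 0 || gc_max > 1 || gc_min >= gc_max) stop("invalid GC bounds")
    if (min_fragment <= 0 || max_fragment <= min_fragment)
      stop("invalid fragment bounds")
    if (w_out < 0 || w_in < 0) stop("anchor windows must be >= 0")
  })
  with(cfg$simulate, {
    if (any(c(error_sub, error_ins, error_del) < 0) ||
        any(c(error_sub, error_ins, error_del) > 0.2))
      stop("error rates must lie in [0, 0.2]")
    if (on_target_fraction <= 0 || on_target_fraction > 1)
      stop("on_target_fraction must lie in (0, 1]")
  })
  with(cfg$call, {
    if (tol < 0 || min_del <= 0 || min_support < 0) stop("invalid [call] thresholds")
    if (id_min < 0 || id_min > 1) stop("id_min must lie in [0, 1]")
  })
  structure(cfg, class = "castsv_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may define sections `design`, `digest`, `simulate`, `call`,
#' `report` and a top-level `seed`; unknown sections or keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `"castsv_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("design", "digest", "simulate", "call", "report", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  pipeline_config(design = y$design %||% list(), digest = y$digest %||% list(),
                  simulate = y$simulate %||% list(), call = y$call %||% list(),
                  report = y$report %||% list(), seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
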