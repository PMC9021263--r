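# Optical-mapping SV call catalog: the intervals + type + zygosity that seed
# guide design. Two tabular dialects are supported: plain BED (0-based
# half-open, columns 7-8 carrying type and zygosity) and "smap_min", a
# documented minimal header-tagged dialect (1-based inclusive) standing in
# for vendor SMAP exports.

SV_TYPES <- c("deletion", "insertion", "inversion", "duplication", "translocation")
ZYGOSITIES <- c("het", "hom", "unknown")

#' Construct one optical-mapping SV record
#'
#' @param sv_id Unique identifier.
#' @param interval [gi()] locus on the reference contig. For insertions this
#'   is the locus the optical map assigns on the contig, distinct from the
#'   estimated inserted length.
#' @param sv_type One of deletion, insertion, inversion, duplication,
#'   translocation.
#' @param size_estimate Estimated SV size in bp; defaults to the interval
#'   length for deletions and inversions. For insertions: the estimated
#'   inserted length.
#' @param zygosity "het", "hom" or "unknown".
#' @param source Free-text provenance.
#' @return A list of class `"sv_record"`.
#' @export
sv_record <- function(sv_id, interval, sv_type,
                      size_estimate = NULL, zygosity = "unknown", source = "") {
  stopifnot(is.character(sv_id), length(sv_id) == 1L, nzchar(sv_id),
            inherits(interval, "gi"))
  sv_type <- match.arg(sv_type, SV_TYPES)
  zygosity <- match.arg(zygosity, ZYGOSITIES)
  if (is.null(size_estimate)) {
    if (!sv_type %in% c("deletion", "inversion"))
      stop("size_estimate required for sv_type '", sv_type, "'")
    size_estimate <- gi_length(interval)
  }
  if (size_estimate <= 0) stop("size_estimate must be > 0")
  structure(list(sv_id = sv_id, interval = interval, sv_type = sv_type,
                 size_estimate = as.numeric(size_estimate),
                 zygosity = zygosity, source = source),
            class = "sv_record")
}

#' Build an SV catalog from records
#' @param records List of [sv_record()] objects.
#' @param reference_name Name of the reference the coordinates refer to.
#' @return Object of class `"sv_catalog"`.
#' @export
sv_catalog <- function(records, reference_name = "") {
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE, "sv_record")))
  ids <- vapply(records, `[[`, character(1), "sv_id")
  if (anyDuplicated(ids))
    stop("duplicate sv_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records, reference_name = reference_name),
            class = "sv_catalog")
}

#' @export
print.sv_catalog <- function(x, ...) {
  s <- summarize_catalog(x)
  cat(sprintf("<sv_catalog> %d SV call(s) on '%s'\n", s$total, x$reference_name))
  for (t in names(s$counts)) if (s$counts[[t]] > 0)
    cat(sprintf("  %-13s %d\n", t, s$counts[[t]]))
  invisible(x)
}

#' @export
length.sv_catalog <- function(x) length(x$records)

#' Catalog as a data frame (1-based reporting coordinates)
#' @param x An `sv_catalog`.
#' @param ... Unused.
#' @return data.frame with one row per record.
#' @method as.data.frame sv_catalog
#' @export
as.data.frame.sv_catalog <- function(x, ...) {
  do.call(rbind, lapply(x$records, function(r) {
    rc <- to_report_coords(r$interval)
    data.frame(sv_id = r$sv_id, chrom = rc$chrom, start = rc$start, end = rc$end,
               sv_type = r$sv_type, size_estimate = r$size_estimate,
               zygosity = r$zygosity, source = r$source,
               stringsAsFactors = FALSE)
  }))
}

#' Parse an SV call table
#'
#' @param path File path.
#' @param dialect `"bed"` (0-based half-open; columns chrom, start, end, name,
#'   score, strand, sv_type, zygosity with "." for unknown) or `"smap_min"`
#'   (tab-delimited, header line `#chrom start end type size zygosity id`,
#'   1-based inclusive coordinates, converted on ingest).
#' @param reference_name Stored on the catalog.
#' @return An [sv_catalog()].
#' @export
parse_sv_table <- function(path, dialect = c("bed", "smap_min"),
                           reference_name = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("SV table not found: ", path)
  lines <- readLines(path)
  recs <- list()
  if (dialect == "bed") {
    body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
    for (i in body) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 8L)
        stop("malformed BED row at line ", i, ": expected 8 columns, got ", length(f))
      start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
      if (is.na(start) || is.na(end)) stop("non-numeric coordinates at line ", i)
      if (start >= end) stop("coordinate order violation at line ", i,
                             " (start >= end)")
      if (!f[7] %in% SV_TYPES) stop("unknown sv_type '", f[7], "' at line ", i)
      zyg <- if (f[8] == ".") "unknown" else f[8]
      if (!zyg %in% ZYGOSITIES) stop("unknown zygosity '", f[8], "' at line ", i)
      size <- suppressWarnings(as.numeric(f[5]))
      size <- if (is.na(size) || size <= 0) NULL else size
      if (f[7] == "insertion" && is.null(size))
        stop("insertion row at line ", i, " needs a positive size in the score column")
      recs[[length(recs) + 1L]] <-
        sv_record(f[4], gi(f[1], start, end), f[7], size, zyg, source = "bed")
    }
  } else {
    if (length(lines) == 0L || lines[[1]] != "#chrom\tstart\tend\ttype\tsize\tzygosity\tid")
      stop("smap_min file must begin with header '#chrom\\tstart\\tend\\ttype\\tsize\\tzygosity\\tid'")
    for (i in seq_along(lines)[-1]) {
      if (!nzchar(lines[[i]])) next
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) != 7L) stop("malformed smap_min row at line ", i)
      start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
      if (is.na(start) || is.na(end)) stop("non-numeric coordinates at line ", i)
      if (start > end) stop("coordinate order violation at line ", i, " (start > end)")
      if (!f[4] %in% SV_TYPES) stop("unknown sv_type '", f[4], "' at line ", i)
      if (!f[6] %in% ZYGOSITIES) stop("unknown zygosity '", f[6], "' at line ", i)
      size <- suppressWarnings(as.numeric(f[5]))
      size <- if (is.na(size) || size <= 0) NULL else size
      recs[[length(recs) + 1L]] <-
        sv_record(f[7], from_report_coords(f[1], start, end), f[4], size, f[6],
                  source = "smap_min")
    }
  }
  sv_catalog(recs, reference_name)
}

#' Write an SV catalog in a supported dialect
#' @param catalog An [sv_catalog()].
#' @param path Output path.
#' @param dialect `"bed"` or `"smap_min"`.
#' @export
write_sv_table <- function(catalog, path, dialect = c("bed", "smap_min")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(catalog, "sv_catalog"))
  lines <- character(0)
  if (dialect == "smap_min")
    lines <- "#chrom\tstart\tend\ttype\tsize\tzygosity\tid"
  for (r in catalog$records) {
    if (dialect == "bed") {
      zyg <- if (r$zygosity == "unknown") "." else r$zygosity
      lines <- c(lines, paste(r$interval$chrom, r$interval$start, r$interval$end,
                              r$sv_id, r$size_estimate, "+", r$sv_type, zyg,
                              sep = "\t"))
    } else {
      rc <- to_report_coords(r$interval)
      lines <- c(lines, paste(rc$chrom, rc$start, rc$end, r$sv_type,
                              r$size_estimate, r$zygosity, r$sv_id, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Filter a catalog by size and SV class
#'
#' Size filtering is inclusive: `min_size = 2000` keeps calls of exactly
#' 2 kbp ("2 kbp or longer"). Record order is preserved; idempotent.
#'
#' @param catalog An [sv_catalog()].
#' @param min_size Minimum `size_estimate` in bp (default 2000).
#' @param types SV classes to keep (default: all).
#' @return Filtered [sv_catalog()].
#' @export
filter_catalog <- function(catalog, min_size = 2000, types = SV_TYPES) {
  stopifnot(inherits(catalog, "sv_catalog"), min_size >= 0)
  if (length(types) == 0L) stop("'types' must not be empty")
  types <- match.arg(types, SV_TYPES, several.ok = TRUE)
  keep <- vapply(catalog$records, function(r)
    r$size_estimate >= min_size && r$sv_type %in% types, logical(1))
  sv_catalog(catalog$records[keep], catalog$reference_name)
}

#' Per-class counts of a catalog
#' @param catalog An [sv_catalog()].
#' @return List with `counts` (named vector over all SV classes, zeros
#'   included) and `total` (equal to the number of records).
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "sv_catalog"))
  counts <- stats::setNames(integer(length(SV_TYPES)), SV_TYPES)
  for (r in catalog$records) counts[[r$sv_type]] <- counts[[r$sv_type]] + 1L
  list(counts = counts, total = sum(counts))
}
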