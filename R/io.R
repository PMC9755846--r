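#' Read a deletion cohort from a BED-like file
#'
#' Two explicit dialects are supported; auto-detection is refused to
#' prevent silent off-by-one coordinate errors.
#' * `"bed0"`: whitespace/tab separated BED3+ — `chrom`, `start`
#'   (0-based), `end` (half-open), optional `name` (sample id),
#'   `source`, `zygosity`. Coordinates are converted to 1-based
#'   inclusive: `start + 1`, `end`.
#' * `"tsv1"`: tab-separated with header `sample_id`, `chrom`, `start`,
#'   `end` (1-based inclusive, as coordinates are printed), optional
#'   `source`, `zygosity`.
#'
#' @param path File path.
#' @param dialect `"bed0"` or `"tsv1"` (no default on purpose).
#' @param locus Analysis window; defaults to the span of the records on
#'   their (single) chromosome.
#' @param genome_build Build tag, default `"hg19"`.
#' @return A [deletion_cohort()].
#' @export
read_deletion_bed <- function(path, dialect = c("bed0", "tsv1"),
                              locus = NULL, genome_build = "hg19") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed0") {
    raw <- utils::read.table(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "sample_id", "source",
                                           "zygosity")[1:count_fields(path)],
                             fill = TRUE)
    if (nrow(raw) == 0L) stop("empty file: ", path)
    if (!"sample_id" %in% names(raw))
      raw$sample_id <- sprintf("row%04d", seq_len(nrow(raw)))
    rec <- data.frame(sample_id = as.character(raw$sample_id),
                      chrom = raw$chrom,
                      start = raw$start + 1,   # 0-based -> 1-based
                      end = raw$end,
                      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (nrow(raw) == 0L) stop("empty file: ", path)
    needed <- c("sample_id", "chrom", "start", "end")
    if (!all(needed %in% names(raw)))
      stop("tsv1 file must have header columns ",
           paste(needed, collapse = ", "))
    rec <- raw[, needed]
    rec$sample_id <- as.character(rec$sample_id)
  }
  if ("source" %in% names(raw)) rec$source <- raw$source
  if ("zygosity" %in% names(raw)) rec$zygosity <- raw$zygosity
  bad <- which(rec$end < rec$start)
  if (length(bad))
    stop("coordinate inversion (end < start) at line ", bad[1L],
         " of ", path)
  if (is.null(locus)) {
    chroms <- unique(rec$chrom)
    if (length(chroms) != 1L)
      stop("records span several chromosomes; supply an explicit locus")
    locus <- genomic_interval(chroms, min(rec$start), max(rec$end))
  }
  deletion_cohort(rec, locus, genome_build)
}

count_fields <- function(path) {
  n <- utils::count.fields(path)
  n <- n[!is.na(n)]
  if (!length(n)) stop("empty file: ", path)
  min(max(n), 6L)
}

#' Write a deletion cohort to a BED-like file
#' @param cohort A [deletion_cohort()].
#' @param path Output path.
#' @param dialect `"bed0"` (0-based half-open, no header) or `"tsv1"`
#'   (1-based inclusive, header).
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(cohort, path, dialect = c("bed0", "tsv1")) {
  dialect <- match.arg(dialect)
  rec <- cohort$records
  if (dialect == "bed0") {
    out <- data.frame(chrom = rec$chrom, start = rec$start - 1,
                      end = rec$end, name = rec$sample_id,
                      source = rec$source, zygosity = rec$zygosity)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    out <- rec[, c("sample_id", "chrom", "start", "end", "source",
                   "zygosity")]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a long-format Ct plate CSV
#'
#' Columns `sample_id`, `assay` (`target`/`reference`), `replicate`,
#' `ct`; the string `"NA"` (or an empty field) encodes no
#' amplification.
#'
#' @param path CSV path.
#' @return Plate data frame for [quantify_samples()].
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate$ct <- suppressWarnings(as.numeric(plate$ct))
  check_plate(plate)
}

#' Write a Ct plate CSV
#' @param plate Plate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(plate, path) {
  check_plate(plate)
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON report for a CDR result
#'
#' Stable field ordering, fixed precision (proportions 3 dp, kb 1 dp),
#' so identical runs produce byte-identical reports.
#'
#' @param cdr A `cdr_result` from [find_cdr()].
#' @param path Output path (`.json`).
#' @param warnings Character vector of run warnings (serialized even
#'   when empty).
#' @return `path`, invisibly.
#' @export
write_cdr_report <- function(cdr, path, warnings = character()) {
  fmt_region <- function(r)
    list(chrom = r$chrom, start = r$start, end = r$end,
         length_kb = interval_length_kb(r))
  report <- list(
    region = fmt_region(cdr$region),
    support_count = cdr$support_count,
    n_total = cdr$n_total,
    support_fraction = round_half_up(cdr$support_fraction, 3),
    max_depth = cdr$max_depth,
    is_cdr = cdr$is_cdr,
    min_fraction = cdr$min_fraction,
    min_length = cdr$min_length,
    alternates = lapply(cdr$alternates, fmt_region),
    warnings = as.list(warnings))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON report back
#' @param path JSON path.
#' @return Parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
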