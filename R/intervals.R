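#' Genomic interval (1-based, inclusive)
#'
#' Constructs a validated genomic interval. Coordinates are 1-based and
#' inclusive at both ends, matching the convention in which hg19
#' coordinates such as chr9:21,970,277-21,975,386 are printed; BED input
#' (0-based, half-open) is converted on read by [read_deletion_bed()].
#'
#' @param chrom Chromosome name, e.g. `"chr9"`.
#' @param start 1-based inclusive start coordinate (bp).
#' @param end 1-based inclusive end coordinate (bp), `end >= start`.
#' @return An object of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`.
#' @examples
#' cdr <- genomic_interval("chr9", 21970277, 21975386)
#' interval_length_kb(cdr)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing coordinates")
  if (start < 1) stop("start must be >= 1 (coordinates are 1-based)")
  if (end < start) stop("end must be >= start")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Interval length in base pairs
#' @param interval A [genomic_interval()].
#' @return Length in bp (`end - start + 1`).
#' @export
interval_length <- function(interval) {
  interval$end - interval$start + 1
}

#' Interval length in kilobases, rounded half-up to one decimal
#'
#' The convention used to report CDR sizes: the 5,110 bp region
#' chr9:21,970,277-21,975,386 is reported as 5.1 kb.
#'
#' @inheritParams interval_length
#' @return Length in kb, one decimal place, half-up rounding.
#' @export
interval_length_kb <- function(interval) {
  round_half_up(interval_length(interval) / 1000, 1)
}

#' Round half away from zero
#'
#' Report-formatting convention used throughout (base `round()` rounds
#' half to even): kb lengths to 1 decimal, odds ratios to 2, percents
#' to 1.
#' @param x Numeric vector.
#' @param digits Decimal places, default 0.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Does interval `outer` fully contain interval `inner`?
#' @param outer,inner [genomic_interval()] objects.
#' @return Logical; `FALSE` when on different chromosomes.
#' @export
interval_contains <- function(outer, inner) {
  outer$chrom == inner$chrom &&
    outer$start <= inner$start && outer$end >= inner$end
}

#' Cohort of somatic deletion fragments
#'
#' A deletion cohort bundles one row per deletion fragment (a sample may
#' contribute several fragments) with the analysis window. All fragments
#' must lie on the chromosome of the locus.
#'
#' @param records Data frame with columns `sample_id`, `chrom`, `start`,
#'   `end` and optionally `source` (`"snp_array_estimated"` or
#'   `"sequencing_base_resolution"`) and `zygosity` (`"homozygous"`,
#'   `"hemizygous"`, `"unknown"`). Coordinates 1-based inclusive.
#' @param locus A [genomic_interval()]: the analysis window.
#' @param genome_build Build tag carried through reports, default `"hg19"`.
#' @return A `deletion_cohort` object.
#' @export
deletion_cohort <- function(records, locus, genome_build = "hg19") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty cohort")
  needed <- c("sample_id", "chrom", "start", "end")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  if (!inherits(locus, "genomic_interval"))
    stop("locus must be a genomic_interval")
  if (!"source" %in% names(records)) records$source <- "unknown"
  if (!"zygosity" %in% names(records)) records$zygosity <- "unknown"
  if (any(!nzchar(records$sample_id)))
    stop("sample_id must be non-empty")
  off <- which(records$chrom != locus$chrom)
  if (length(off))
    stop(sprintf("record %d (sample %s) is on %s, not locus chromosome %s",
                 off[1L], records$sample_id[off[1L]],
                 records$chrom[off[1L]], locus$chrom))
  bad <- which(records$end < records$start | records$start < 1)
  if (length(bad))
    stop(sprintf("record %d (sample %s) has invalid coordinates",
                 bad[1L], records$sample_id[bad[1L]]))
  structure(list(records = records, locus = locus,
                 genome_build = genome_build),
            class = "deletion_cohort")
}

#' @export
print.deletion_cohort <- function(x, ...) {
  cat(sprintf("deletion_cohort: %d fragments from %d samples on %s (%s)\n",
              nrow(x$records), length(unique(x$records$sample_id)),
              x$locus$chrom, x$genome_build))
  invisible(x)
}

#' Filter a cohort by zygosity
#' @param cohort A [deletion_cohort()].
#' @param zygosity Character vector of zygosity levels to keep.
#' @return A filtered `deletion_cohort`.
#' @export
filter_zygosity <- function(cohort, zygosity) {
  keep <- cohort$records$zygosity %in% zygosity
  if (!any(keep)) stop("empty cohort")
  deletion_cohort(cohort$records[keep, , drop = FALSE], cohort$locus,
                  cohort$genome_build)
}

#' Sweep-line deletion coverage profile
#'
#' Orders fragment breakpoints (interval starts and `end + 1` positions)
#' and accumulates entering/leaving fragments to obtain the exact step
#' function `x -> #\{fragments covering x\}` — the column-overlay view of
#' a deletion-fragment ladder. Segments are half-open:
#' `depths[i]` holds on `[breakpoints[i], breakpoints[i + 1])`.
#'
#' @param cohort A [deletion_cohort()].
#' @return A `coverage_profile` with sorted `breakpoints`, per-segment
#'   `depths` (length `length(breakpoints) - 1`), and `n_records`.
#' @export
coverage_profile <- function(cohort) {
  stopifnot(inherits(cohort, "deletion_cohort"))
  rec <- cohort$records
  events <- c(rec$start, rec$end + 1)
  delta <- c(rep(1L, nrow(rec)), rep(-1L, nrow(rec)))
  ord <- order(events)
  events <- events[ord]
  delta <- delta[ord]
  bp <- unique(events)
  # depth after processing all events at each breakpoint
  last_at_bp <- cumsum(rle(events)$lengths)
  depth_after <- cumsum(delta)[last_at_bp]
  depths <- as.integer(depth_after[-length(depth_after)])
  structure(list(breakpoints = bp, depths = depths,
                 n_records = nrow(rec), chrom = cohort$locus$chrom),
            class = "coverage_profile")
}

#' Coverage depth at positions
#' @param profile A [coverage_profile()].
#' @param pos Numeric vector of positions (bp).
#' @return Integer vector of deletion depths (0 outside all fragments).
#' @export
depth_at <- function(profile, pos) {
  idx <- findInterval(pos, profile$breakpoints)
  out <- integer(length(pos))
  inside <- idx >= 1L & idx <= length(profile$depths)
  out[inside] <- profile$depths[idx[inside]]
  out
}

#' Find the common deletion region (CDR) of a cohort
#'
#' The CDR candidate is the maximal-depth run of the coverage profile
#' (adjacent equal-depth segments merged). If several disjoint
#' maximal-depth runs exist the longest is returned (ties broken by the
#' smaller start) and all runs are listed in `alternates`. Support is
#' counted by full containment: a fragment supports the region only if
#' it contains every base of it, which can be fewer fragments than the
#' plateau depth when different fragments cover different parts of the
#' plateau.
#'
#' @param cohort A [deletion_cohort()].
#' @param min_fraction Minimum support fraction for a CDR call
#'   (default 0.8).
#' @param min_length Minimum region length in bp for a CDR call
#'   (default 1000).
#' @return A `cdr_result` with `region`, `support_count`, `n_total`,
#'   `support_fraction`, `is_cdr`, `max_depth` and `alternates` (list of
#'   all maximal-depth runs as `genomic_interval`s).
#' @examples
#' rec <- data.frame(sample_id = c("a", "b", "c", "d"),
#'                   chrom = "chr9",
#'                   start = c(100, 200, 250, 700),
#'                   end = c(500, 600, 300, 900))
#' co <- deletion_cohort(rec, genomic_interval("chr9", 1, 1000))
#' find_cdr(co, min_fraction = 0.75, min_length = 10)
#' @export
find_cdr <- function(cohort, min_fraction = 0.8, min_length = 1000) {
  stopifnot(min_fraction > 0, min_fraction <= 1, min_length >= 1)
  prof <- coverage_profile(cohort)
  dmax <- max(prof$depths)
  runs <- depth_runs(prof, dmax)
  lens <- vapply(runs, interval_length, numeric(1))
  starts <- vapply(runs, function(r) r$start, numeric(1))
  pick <- order(-lens, starts)[1L]
  region <- runs[[pick]]
  n_total <- prof$n_records
  support <- containment_count(cohort, region)
  frac <- support / n_total
  structure(list(
    region = region,
    support_count = support,
    n_total = n_total,
    support_fraction = frac,
    max_depth = dmax,
    is_cdr = frac >= min_fraction && interval_length(region) >= min_length,
    min_fraction = min_fraction,
    min_length = min_length,
    alternates = runs
  ), class = "cdr_result")
}

# Maximal runs of segments at a given depth, merged across adjacency.
depth_runs <- function(profile, depth) {
  at <- profile$depths == depth
  r <- rle(at)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- list()
  chrom <- profile$chrom
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts_idx[k]; j <- ends_idx[k]
    runs[[length(runs) + 1L]] <- genomic_interval(
      if (is.null(chrom)) "." else chrom,
      profile$breakpoints[i],
      profile$breakpoints[j + 1L] - 1)
  }
  runs
}

containment_count <- function(cohort, region) {
  rec <- cohort$records
  sum(rec$start <= region$start & rec$end >= region$end)
}

#' @export
print.cdr_result <- function(x, ...) {
  cat(sprintf(
    "CDR %s: %s:%s-%s (%.1f kb), support %d/%d = %.3f, max depth %d\n",
    if (x$is_cdr) "found" else "not called",
    x$region$chrom,
    format(x$region$start, big.mark = ",", scientific = FALSE),
    format(x$region$end, big.mark = ",", scientific = FALSE),
    interval_length_kb(x$region), x$support_count, x$n_total,
    x$support_fraction, x$max_depth))
  invisible(x)
}

#' PCR amplicon
#' @param name Assay/amplicon name.
#' @param interval A [genomic_interval()]; the product size equals its
#'   length.
#' @return An `amplicon` object with `name`, `interval`, `product_size`.
#' @export
amplicon <- function(name, interval) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(interval, "genomic_interval"))
  structure(list(name = name, interval = interval,
                 product_size = interval_length(interval)),
            class = "amplicon")
}

#' Fraction of deletion fragments fully containing an amplicon
#'
#' Containment, not overlap: a fragment counts only if the whole
#' amplicon lies within the deleted interval, i.e. the assay target is
#' lost on that fragment.
#'
#' @param cohort A [deletion_cohort()].
#' @param amp An [amplicon()].
#' @return List with `count`, `n_total` and `fraction`.
#' @export
amplicon_coverage <- function(cohort, amp) {
  stopifnot(inherits(cohort, "deletion_cohort"), inherits(amp, "amplicon"))
  rec <- cohort$records
  hit <- rec$chrom == amp$interval$chrom &
    rec$start <= amp$interval$start & rec$end >= amp$interval$end
  list(count = sum(hit), n_total = nrow(rec),
       fraction = sum(hit) / nrow(rec))
}

#' Fraction of fragments containing at least one of several amplicons
#' @param cohort A [deletion_cohort()].
#' @param amplicons Non-empty list of [amplicon()]s.
#' @return List with `count`, `n_total` and `fraction` of the union.
#' @export
combined_amplicon_coverage <- function(cohort, amplicons) {
  stopifnot(length(amplicons) >= 1L)
  rec <- cohort$records
  hit <- rep(FALSE, nrow(rec))
  for (amp in amplicons) {
    stopifnot(inherits(amp, "amplicon"))
    hit <- hit | (rec$chrom == amp$interval$chrom &
                    rec$start <= amp$interval$start &
                    rec$end >= amp$interval$end)
  }
  list(count = sum(hit), n_total = nrow(rec),
       fraction = sum(hit) / nrow(rec))
}
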