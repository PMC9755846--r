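#' @name synth
#' @title Seeded synthetic generators
#'
#' @description
#' Every pipeline stage has a generator that emulates the statistical
#' structure the analysis assumes: deletion cohorts with a planted
#' common deletion region, duplex qPCR plates driven by true copy
#' numbers under additive Gaussian cycle noise, and clinical call
#' tables from a logistic model with planted odds ratios. All
#' generators are pure functions of their arguments including the seed.
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a deletion cohort with a planted CDR
#'
#' Each fragment contains the planted region with probability
#' `containment_fraction`; containing fragments have their breakpoints
#' scattered uniformly on the integer flanks within
#' `breakpoint_spread` bp of the region (start on
#' `[cdr$start - spread, cdr$start]`, end on
#' `[cdr$end, cdr$end + spread]`, clipped to the locus). Non-containing
#' fragments are placed entirely in the outer flank beyond the
#' breakpoint spread, so they miss the region and never stack deletion
#' depth on top of the near-flank coverage of the containing
#' fragments. With `anchor_endpoints = TRUE` (default) the first two
#' containing fragments start exactly at `cdr$start` / end exactly at
#' `cdr$end`; [find_cdr()] then recovers the planted endpoints exactly
#' whenever at least two fragments contain the region and containing
#' fragments outnumber non-containing ones. `exact_count = TRUE`
#' plants exactly `round(containment_fraction * n_fragments)`
#' containing fragments instead of Bernoulli sampling.
#'
#' @param n_fragments Number of deletion fragments (>= 1).
#' @param locus Analysis window, a [genomic_interval()].
#' @param planted_cdr The planted region, strictly inside `locus` with
#'   at least 1 bp of flank on each side.
#' @param containment_fraction Probability a fragment contains the
#'   planted region, default 0.9 (the fraction observed for the 5.1 kb
#'   region across 92 base-resolution deletion fragments).
#' @param breakpoint_spread Scatter scale (bp) of containing-fragment
#'   breakpoints around the planted region, default 30000.
#' @param seed Integer seed, default 20220917.
#' @param source Source tag for the records.
#' @param anchor_endpoints Anchor the first two containing fragments at
#'   the planted endpoints (default `TRUE`).
#' @param exact_count Plant a deterministic number of containing
#'   fragments (default `FALSE`).
#' @return A [deletion_cohort()]; attribute `contains_cdr` is the
#'   logical planting vector.
#' @export
gen_deletion_cohort <- function(n_fragments,
                                locus = genomic_interval("chr9", 21800000, 22200000),
                                planted_cdr = genomic_interval("chr9", 21970277, 21975386),
                                containment_fraction = 0.9,
                                breakpoint_spread = 30000,
                                seed = 20220917,
                                source = "sequencing_base_resolution",
                                anchor_endpoints = TRUE,
                                exact_count = FALSE) {
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  stopifnot(containment_fraction >= 0, containment_fraction <= 1,
            breakpoint_spread >= 1)
  if (planted_cdr$chrom != locus$chrom ||
      planted_cdr$start <= locus$start || planted_cdr$end >= locus$end)
    stop("planted CDR must leave a flank inside the locus on both sides")
  near_lo <- max(locus$start, planted_cdr$start - breakpoint_spread)
  near_hi <- min(locus$end, planted_cdr$end + breakpoint_spread)
  # outer flank for non-containing fragments, disjoint from the
  # breakpoint-scatter zone of the containing fragments
  outer_left <- c(locus$start, near_lo - 1)
  outer_right <- c(near_hi + 1, locus$end)
  has_left <- outer_left[2] >= outer_left[1]
  has_right <- outer_right[2] >= outer_right[1]
  with_seed(seed, {
    contains <- if (exact_count) {
      k <- round(containment_fraction * n_fragments)
      sample(rep(c(TRUE, FALSE), c(k, n_fragments - k)))
    } else {
      stats::runif(n_fragments) < containment_fraction
    }
    if (any(!contains) && !has_left && !has_right)
      stop("locus leaves no outer flank for non-containing fragments; ",
           "reduce breakpoint_spread or enlarge the locus")
    starts <- ends <- numeric(n_fragments)
    n_anchored <- 0L
    for (i in seq_len(n_fragments)) {
      if (contains[i]) {
        starts[i] <- sample_int(near_lo, planted_cdr$start)
        ends[i] <- sample_int(planted_cdr$end, near_hi)
        if (anchor_endpoints && n_anchored == 0L) {
          starts[i] <- planted_cdr$start
          n_anchored <- 1L
        } else if (anchor_endpoints && n_anchored == 1L) {
          ends[i] <- planted_cdr$end
          n_anchored <- 2L
        }
      } else {
        left <- if (has_left && has_right) stats::runif(1) < 0.5 else has_left
        rng <- if (left) outer_left else outer_right
        starts[i] <- sample_int(rng[1], rng[2])
        ends[i] <- sample_int(starts[i], rng[2])
      }
    }
    rec <- data.frame(
      sample_id = sprintf("SYN%03d", seq_len(n_fragments)),
      chrom = locus$chrom, start = starts, end = ends,
      source = source, zygosity = "homozygous",
      stringsAsFactors = FALSE)
    out <- deletion_cohort(rec, locus)
    attr(out, "contains_cdr") <- contains
    out
  })
}

sample_int <- function(lo, hi) {
  if (hi < lo) stop("empty sampling range")
  lo + floor(stats::runif(1) * (hi - lo + 1))
}

#' Generate a duplex qPCR plate from true copy numbers
#'
#' Ct model: `Ct = baseline - log2(effective_copies / 2) + N(0, sd)`
#' independently per well and channel. The effective target copy
#' number of a spike-in mixture with null fraction `f` is
#' `2 (1 - f) (true_copies / 2)` (mass fractions treated as copy
#' fractions); the reference gene always has 2 copies. Zero effective
#' copies yield `NA` Ct (no amplification).
#'
#' @param samples Data frame with columns `sample_id`, `true_copies`
#'   (target copies per diploid genome), and optionally `null_fraction`
#'   (default 0).
#' @param replicates Wells per sample, default 3 (assays are run in
#'   triplicate).
#' @param ct_noise_sd Gaussian cycle-noise SD, default 0.1.
#' @param baseline_ct Ct of a two-copy template, default 28.
#' @param seed Integer seed, default 20220917.
#' @return Long-format plate data frame (`sample_id`, `assay`,
#'   `replicate`, `ct`) accepted by [quantify_samples()].
#' @export
gen_qpcr_plate <- function(samples, replicates = 3, ct_noise_sd = 0.1,
                           baseline_ct = 28, seed = 20220917) {
  stopifnot(all(c("sample_id", "true_copies") %in% names(samples)),
            replicates >= 2, ct_noise_sd >= 0)
  if (!"null_fraction" %in% names(samples)) samples$null_fraction <- 0
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(samples)), function(i) {
      eff <- 2 * (1 - samples$null_fraction[i]) *
        (samples$true_copies[i] / 2)
      ct_t <- if (eff <= 0) rep(NA_real_, replicates) else {
        baseline_ct - log2(eff / 2) +
          stats::rnorm(replicates, 0, ct_noise_sd)
      }
      ct_r <- baseline_ct + stats::rnorm(replicates, 0, ct_noise_sd)
      data.frame(
        sample_id = samples$sample_id[i],
        assay = rep(c("target", "reference"), each = replicates),
        replicate = rep(seq_len(replicates), 2),
        ct = c(ct_t, ct_r),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a spike-in mixture series
#'
#' Convenience wrapper over [gen_qpcr_plate()] producing the
#' `null_fraction`-keyed series consumed by [mixture_linearity()] and
#' [detection_limit()]. The default fractions are the spike-in design
#' 0, 10%, 20%, 25%, 30% of zero-copy DNA into a two-copy background.
#'
#' @param null_fractions Proportions of zero-copy DNA, must include 0.
#' @inheritParams gen_qpcr_plate
#' @return Data frame with columns `null_fraction`, `assay`,
#'   `replicate`, `ct`.
#' @export
gen_mixture_series <- function(null_fractions = c(0, 0.10, 0.20, 0.25, 0.30),
                               replicates = 3, ct_noise_sd = 0.1,
                               baseline_ct = 28, seed = 20220917) {
  if (!any(null_fractions == 0))
    stop("series must include the 0% control")
  samples <- data.frame(
    sample_id = sprintf("MIX_%02d", round(100 * null_fractions)),
    true_copies = 2, null_fraction = null_fractions,
    stringsAsFactors = FALSE)
  plate <- gen_qpcr_plate(samples, replicates, ct_noise_sd, baseline_ct,
                          seed)
  plate$null_fraction <-
    samples$null_fraction[match(plate$sample_id, samples$sample_id)]
  plate[, c("null_fraction", "assay", "replicate", "ct")]
}

#' Generate a template titration series
#'
#' Ct decreases by one cycle per template doubling at perfect
#' efficiency; both assays share the titration response.
#'
#' @param amounts_ng Template amounts per reaction, default the
#'   two-fold series 10, 5, 2.5, 1.25, 0.63 ng.
#' @param reference_ng Amount at which Ct equals `baseline_ct`.
#' @inheritParams gen_qpcr_plate
#' @return Data frame with columns `amount_ng`, `assay`, `replicate`,
#'   `ct` for [titration_efficiency()].
#' @export
gen_titration_series <- function(amounts_ng = c(10, 5, 2.5, 1.25, 0.63),
                                 replicates = 3, ct_noise_sd = 0.1,
                                 baseline_ct = 28, reference_ng = 10,
                                 seed = 20220917) {
  stopifnot(length(amounts_ng) >= 3, all(amounts_ng > 0))
  with_seed(seed, {
    rows <- lapply(amounts_ng, function(a) {
      mu <- baseline_ct - log2(a / reference_ng)
      data.frame(
        amount_ng = a,
        assay = rep(c("target", "reference"), each = replicates),
        replicate = rep(seq_len(replicates), 2),
        ct = mu + stats::rnorm(2 * replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a clinical call table from a logistic model
#'
#' A binary covariate is drawn at the stated prevalence and the
#' deletion call from `logit P(call) = intercept + log(or) * covariate`,
#' planting a known odds ratio between call and covariate.
#'
#' @param n_samples Number of samples.
#' @param prevalence Covariate prevalence in (0, 1), default 0.5.
#' @param planted_or Planted odds ratio, default 1 (no association).
#' @param baseline_logit Intercept of the logistic model, default
#'   `qlogis(0.35)` (a call rate near the observed 36.7%).
#' @param seed Integer seed, default 20220917.
#' @return Data frame with `sample_id`, logical `call`, and factor-free
#'   character `covariate` (`"positive"`/`"negative"`).
#' @export
gen_clinical_table <- function(n_samples, prevalence = 0.5,
                               planted_or = 1,
                               baseline_logit = stats::qlogis(0.35),
                               seed = 20220917) {
  stopifnot(n_samples >= 1, prevalence > 0, prevalence < 1,
            planted_or > 0)
  with_seed(seed, {
    x <- stats::runif(n_samples) < prevalence
    p <- stats::plogis(baseline_logit + log(planted_or) * x)
    call <- stats::runif(n_samples) < p
    data.frame(sample_id = sprintf("CLN%05d", seq_len(n_samples)),
               call = call,
               covariate = ifelse(x, "positive", "negative"),
               stringsAsFactors = FALSE)
  })
}

# Per-covariate level counts within each of the four call cells
# (both+, P16-Light only, P14-qPCR only, neither), in that cell order.
# Derived from the printed per-subgroup positive counts: within a
# subgroup with n samples, a P16-Light positives, b P14-qPCR positives
# and d double positives, the cells are d, a-d, b-d, n-(a+b-d).
# The differentiation grade is missing for 3 of the 139 samples.
table2_cells <- function() {
  list(
    age = list("<60" = c(8, 15, 10, 35), ">=60" = c(11, 17, 15, 28)),
    sex = list(Male = c(15, 25, 18, 43), Female = c(4, 7, 7, 20)),
    location = list(Cardiac = c(2, 7, 1, 8),
                    Noncardiac = c(17, 25, 24, 55)),
    differentiation = list(Poor = c(12, 21, 18, 48),
                           `Well/moderate` = c(7, 9, 7, 14),
                           `NA` = c(0, 2, 0, 1)),
    stage = list(`I-II` = c(4, 7, 12, 23), III = c(5, 9, 3, 20),
                 IV = c(10, 16, 10, 20)),
    invasion = list(`T1-2` = c(5, 6, 8, 8), T3 = c(9, 19, 10, 41),
                    T4 = c(5, 7, 7, 14)),
    lymph_metastasis = list(Negative = c(7, 9, 11, 24),
                            Positive = c(12, 23, 14, 39)),
    distant_metastasis = list(Negative = c(11, 20, 22, 54),
                              Positive = c(8, 12, 3, 9))
  )
}

#' Deterministic 139-sample call table with the published margins
#'
#' Emits a per-sample table whose two assay calls and eight
#' clinicopathological covariates reproduce, for every covariate
#' subgroup, the printed positive counts of the gastric-carcinoma
#' association table: 51 P16-Light positives, 44 P14-qPCR positives,
#' 19 double positives (hence 76 OR-merged) among 139 samples, with
#' e.g. the distant-metastasis cross-table (20, 12, 31, 76). The
#' differentiation grade is missing for 3 samples, as in the published
#' table. Fully deterministic; the joint distribution across covariates
#' is otherwise arbitrary (covariates are assigned independently within
#' each call cell).
#'
#' @return Data frame with `sample_id`, logical `call_p16light`,
#'   `call_p14`, and character covariate columns (`age`, `sex`,
#'   `location`, `differentiation`, `stage`, `invasion`,
#'   `lymph_metastasis`, `distant_metastasis`).
#' @export
table2_preset <- function() {
  cell_sizes <- c(both = 19, p16_only = 32, p14_only = 25, neither = 63)
  cell_of <- rep(names(cell_sizes), cell_sizes)
  out <- data.frame(
    sample_id = sprintf("GC%03d", seq_len(139)),
    call_p16light = cell_of %in% c("both", "p16_only"),
    call_p14 = cell_of %in% c("both", "p14_only"),
    stringsAsFactors = FALSE)
  for (cov in names(table2_cells())) {
    counts <- table2_cells()[[cov]]
    col <- character(139)
    for (cell_idx in seq_along(cell_sizes)) {
      idx <- which(cell_of == names(cell_sizes)[cell_idx])
      lv <- unlist(lapply(names(counts), function(lev)
        rep(lev, counts[[lev]][cell_idx])))
      stopifnot(length(lv) == length(idx))
      col[idx] <- lv
    }
    col[col == "NA"] <- NA_character_
    out[[cov]] <- col
  }
  out
}
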