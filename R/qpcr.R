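#' @name qpcr
#' @title Relative copy-number quantification from multiplex qPCR Ct data
#'
#' @description
#' The quantification chain implemented here mirrors a duplex TaqMan
#' assay in which a target amplicon (e.g. the 129-bp CDKN2A intron-2
#' amplicon inside the 5.1 kb common deletion region) is amplified
#' together with a reference-gene amplicon (GAPDH) in every well, in
#' replicate. Wells that fail to amplify carry `NA` Ct ("no
#' amplification"). The chain is: replicate aggregation, reference-gene
#' informativeness gating (mean GAPDH Ct <= 34 cycles), per-replicate
#' delta-Ct, delta-delta-Ct relative copy number against a calibrator
#' (the paired normal tissue, or the 100% two-copy control), and a
#' two-sided t-test against the paired reference to call somatic
#' deletion or amplification.
NULL

#' Aggregate replicate Ct values
#'
#' `NA` Ct values (no amplification) are excluded from the mean but
#' counted in `n_total`.
#'
#' @param ct Numeric vector of replicate Ct values; `NA` = no
#'   amplification.
#' @return List with `mean`, `sd` (sample SD), `n_used`, `n_total`.
#' @export
aggregate_replicates <- function(ct) {
  n_total <- length(ct)
  ct_ok <- ct[!is.na(ct)]
  if (length(ct_ok) < 2L)
    stop("insufficient replicates: need >= 2 amplified wells, got ",
         length(ct_ok))
  if (any(ct_ok <= 0)) stop("Ct values must be positive")
  list(mean = mean(ct_ok), sd = stats::sd(ct_ok),
       n_used = length(ct_ok), n_total = n_total)
}

#' Reference-gene informativeness gate
#'
#' A sample qualifies for copy-number calling only when its mean
#' reference-gene (GAPDH) Ct is at or below the cutoff — enough intact
#' input DNA to quantify against. The boundary is inclusive: exactly
#' 34.0 cycles is informative.
#'
#' @param mean_ct_reference Mean reference-gene Ct over >= 2 replicates;
#'   `NA` (no amplification) is non-informative.
#' @param cutoff Informativeness cutoff in cycles, default 34.
#' @return Logical.
#' @export
is_informative <- function(mean_ct_reference, cutoff = 34.0) {
  if (length(mean_ct_reference) != 1L) stop("expected a single mean Ct")
  !is.na(mean_ct_reference) && mean_ct_reference <= cutoff
}

#' Delta-delta-Ct relative copy number
#'
#' `efficiency^-(delta_ct_sample - delta_ct_calibrator)`, the classic
#' comparative-Ct quantity with the calibrator at 1. The deletion
#' proportion is `1 - rcn`; negative values signal copy gain.
#'
#' @param delta_ct_sample Target-minus-reference Ct of the sample.
#' @param delta_ct_calibrator Target-minus-reference Ct of the
#'   calibrator (paired normal or two-copy control).
#' @param efficiency Amplification factor per cycle, in (1, 2.2];
#'   default 2 (perfect doubling, validated by titration).
#' @return Relative copy number (vectorized over `delta_ct_sample`).
#' @export
relative_copy_number <- function(delta_ct_sample, delta_ct_calibrator,
                                 efficiency = 2.0) {
  if (efficiency <= 1 || efficiency > 2.2)
    stop("efficiency must be in (1, 2.2]")
  efficiency^-(delta_ct_sample - delta_ct_calibrator)
}

# Per-replicate delta-Ct for one sample from a plate table.
# Replicates are paired by sorted replicate index (duplex wells); when
# target/reference replicate counts differ, each target replicate is
# paired with the mean reference Ct.
sample_delta_cts <- function(plate, sample_id) {
  rows <- plate[plate$sample_id == sample_id, , drop = FALSE]
  tg <- rows[rows$assay == "target", , drop = FALSE]
  rf <- rows[rows$assay == "reference", , drop = FALSE]
  tg <- tg[order(tg$replicate), , drop = FALSE]
  rf <- rf[order(rf$replicate), , drop = FALSE]
  ct_t <- tg$ct
  ct_r <- rf$ct
  if (nrow(tg) == nrow(rf) && all(tg$replicate == rf$replicate)) {
    dct <- ct_t - ct_r
  } else {
    dct <- ct_t - mean(ct_r, na.rm = TRUE)
  }
  list(dct = dct, ct_target = ct_t, ct_reference = ct_r)
}

#' Deletion/amplification call from paired replicate measurements
#'
#' Two-sided two-sample Student's t-test (pooled variance) of the
#' sample against its paired
#' reference. By default the test is computed on replicate delta-Ct
#' values, where the additive Gaussian cycle-noise model makes the
#' t-test assumptions hold exactly; `test_space = "rcn"` tests the
#' exponentiated relative copy numbers instead (same ordering, slightly
#' conservative at triplicate sample sizes). Zero-variance inputs
#' (noise-free simulation) make the t statistic undefined; the call then
#' degenerates to p = 0 when the means differ and p = 1 when equal,
#' with a warning.
#'
#' @param sample_values,reference_values Replicate values for tumor and
#'   paired normal: delta-Ct values when `test_space = "dct"`, relative
#'   copy numbers when `"rcn"`. For `"dct"`, larger values mean fewer
#'   copies.
#' @param alpha Per-sample significance level, default 0.05.
#' @param test_space `"dct"` (default) or `"rcn"`.
#' @return List with `call` (`"deletion"`, `"amplification"`,
#'   `"neutral"`), `p_value`, `sample_mean`, `reference_mean` (means on
#'   the rcn scale).
#' @export
call_scnv <- function(sample_values, reference_values, alpha = 0.05,
                      test_space = c("dct", "rcn")) {
  test_space <- match.arg(test_space)
  if (length(sample_values) < 2L || length(reference_values) < 2L)
    stop("insufficient replicates: need >= 2 values per side")
  p <- degenerate_safe_t(sample_values, reference_values)
  if (test_space == "dct") {
    # lower dct = more copies; convert means to the rcn scale for the
    # direction of the call
    s_mean <- 2^-(mean(sample_values) - mean(reference_values))
    r_mean <- 1
  } else {
    s_mean <- mean(sample_values)
    r_mean <- mean(reference_values)
  }
  call <- "neutral"
  if (p < alpha) {
    call <- if (s_mean < r_mean) "deletion" else "amplification"
  }
  list(call = call, p_value = p, sample_mean = s_mean,
       reference_mean = r_mean)
}

# Student's (pooled-variance) t-test robust to zero-variance sides.
# Pooled rather than Welch: replicate sets share the same measurement
# design on both sides, and at n = 3 per side Welch's approximation is
# markedly conservative (empirical size ~0.034 at nominal 0.05) while
# the pooled test is exact under the Gaussian cycle-noise model.
degenerate_safe_t <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx < .Machine$double.eps && vy < .Machine$double.eps) {
    warning("zero-variance replicates; p set by mean comparison")
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Quantify tumor samples against paired normals
#'
#' Runs the full per-sample chain on a long-format plate table: replicate
#' aggregation, GAPDH informativeness gating of both tumor and paired
#' normal, per-replicate delta-Ct, relative copy number with the paired
#' normal as calibrator, and the paired t-test call. A tumor whose
#' target amplicon fails in every replicate while its reference remains
#' informative is called a complete-dropout deletion (p recorded as 0).
#'
#' @param plate Data frame with columns `sample_id`, `assay`
#'   (`"target"`/`"reference"`), `replicate`, `ct` (`NA` = no
#'   amplification).
#' @param pairs Data frame with columns `tumor_id`, `normal_id`.
#' @param alpha Significance level, default 0.05.
#' @param efficiency Amplification factor per cycle, default 2.
#' @param ct_cutoff Reference-gene informativeness cutoff, default 34.
#' @param test_space Passed to [call_scnv()].
#' @return Data frame, one row per tumor: `sample_id`, `normal_id`,
#'   `mean_ct_target`, `mean_ct_reference`, `delta_ct`, `informative`,
#'   `rel_copy_number`, `deletion_proportion`, `p_value`, `call`,
#'   `dropout`.
#' @export
quantify_samples <- function(plate, pairs, alpha = 0.05, efficiency = 2.0,
                             ct_cutoff = 34.0,
                             test_space = c("dct", "rcn")) {
  test_space <- match.arg(test_space)
  check_plate(plate)
  stopifnot(all(c("tumor_id", "normal_id") %in% names(pairs)))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    quantify_one(plate, pairs$tumor_id[i], pairs$normal_id[i],
                 alpha, efficiency, ct_cutoff, test_space)
  })
  do.call(rbind, out)
}

quantify_one <- function(plate, tumor_id, normal_id, alpha, efficiency,
                         ct_cutoff, test_space) {
  row <- function(...) {
    defaults <- list(sample_id = tumor_id, normal_id = normal_id,
                     mean_ct_target = NA_real_, mean_ct_reference = NA_real_,
                     delta_ct = NA_real_, informative = FALSE,
                     rel_copy_number = NA_real_,
                     deletion_proportion = NA_real_, p_value = NA_real_,
                     call = "non_informative", dropout = FALSE)
    mods <- list(...)
    defaults[names(mods)] <- mods
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }
  ts <- sample_delta_cts(plate, tumor_id)
  ns <- sample_delta_cts(plate, normal_id)
  ref_ok <- function(x) sum(!is.na(x)) >= 2L
  if (!ref_ok(ts$ct_reference) || !ref_ok(ns$ct_reference)) return(row())
  t_ref <- aggregate_replicates(ts$ct_reference)
  n_ref <- aggregate_replicates(ns$ct_reference)
  if (!is_informative(t_ref$mean, ct_cutoff) ||
      !is_informative(n_ref$mean, ct_cutoff)) return(row())

  n_dct <- ns$dct[!is.na(ns$dct)]
  cal <- mean(n_dct)

  # complete target dropout in an informative sample: total loss
  if (all(is.na(ts$ct_target))) {
    return(row(mean_ct_reference = t_ref$mean, informative = TRUE,
               rel_copy_number = 0, deletion_proportion = 1,
               p_value = 0, call = "deletion", dropout = TRUE))
  }
  t_dct <- ts$dct[!is.na(ts$dct)]
  if (length(t_dct) < 2L || length(n_dct) < 2L) return(row())
  t_tgt <- aggregate_replicates(ts$ct_target)
  rcn <- relative_copy_number(mean(t_dct), cal, efficiency)
  values <- switch(test_space,
    dct = list(s = t_dct, r = n_dct),
    rcn = list(s = relative_copy_number(t_dct, cal, efficiency),
               r = relative_copy_number(n_dct, cal, efficiency)))
  res <- call_scnv(values$s, values$r, alpha, test_space)
  row(mean_ct_target = t_tgt$mean, mean_ct_reference = t_ref$mean,
      delta_ct = mean(t_dct), informative = TRUE,
      rel_copy_number = rcn, deletion_proportion = 1 - rcn,
      p_value = res$p_value, call = res$call)
}

check_plate <- function(plate) {
  stopifnot(is.data.frame(plate))
  needed <- c("sample_id", "assay", "replicate", "ct")
  missing_cols <- setdiff(needed, names(plate))
  if (length(missing_cols))
    stop("plate lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(plate$assay %in% c("target", "reference")))
    stop("assay must be 'target' or 'reference'")
  invisible(plate)
}

#' Amplification efficiency from a template titration series
#'
#' Least-squares regression of mean Ct on log2(input DNA) per assay. A
#' perfectly efficient PCR loses exactly one cycle per template
#' doubling (slope -1), giving efficiency `2^(-1/slope) = 2`. Also
#' reports the per-amount target-minus-reference delta-Ct, whose
#' constancy across amounts indicates matched amplicon efficiencies
#' (no template inhibition).
#'
#' @param series Data frame with columns `amount_ng`, `assay`
#'   (`"target"`/`"reference"`), `replicate`, `ct`.
#' @return List with per-assay `slope` (cycles per log2 ng),
#'   `efficiency` (fold per cycle), and `delta_ct_by_amount` (data frame
#'   `amount_ng`, `delta_ct`).
#' @export
titration_efficiency <- function(series) {
  stopifnot(all(c("amount_ng", "assay", "replicate", "ct") %in%
                  names(series)))
  amounts <- sort(unique(series$amount_ng))
  if (length(amounts) < 3L)
    stop("need >= 3 distinct template amounts")
  if (log2(max(amounts) / min(amounts)) < 2)
    stop("template amounts must span >= 2 doublings")
  fit_one <- function(assay) {
    sub <- series[series$assay == assay & !is.na(series$ct), , drop = FALSE]
    mean_ct <- tapply(sub$ct, sub$amount_ng, mean)
    x <- log2(as.numeric(names(mean_ct)))
    fit <- stats::lm(as.numeric(mean_ct) ~ x)
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope >= -0.1)
      stop("no amplification response: Ct does not decrease with input")
    list(slope = slope, efficiency = 2^(-1 / slope))
  }
  tg <- fit_one("target")
  rf <- fit_one("reference")
  dct <- vapply(amounts, function(a) {
    sub <- series[series$amount_ng == a, , drop = FALSE]
    mean(sub$ct[sub$assay == "target"], na.rm = TRUE) -
      mean(sub$ct[sub$assay == "reference"], na.rm = TRUE)
  }, numeric(1))
  list(target = tg, reference = rf,
       delta_ct_by_amount = data.frame(amount_ng = amounts,
                                       delta_ct = dct))
}

#' Linearity of measured deletion proportion in a spike-in series
#'
#' For a dilution series of zero-copy DNA spiked into two-copy DNA at
#' known mass fractions, regresses the measured deletion proportion
#' (1 - relative copy number vs the 0% mixture) on the known null
#' fraction. An accurate assay gives slope 1, intercept 0, r ~ 1.
#'
#' @param series Data frame with columns `null_fraction`, `assay`,
#'   `replicate`, `ct`; must contain the 0 fraction (the pure two-copy
#'   calibrator).
#' @param efficiency Amplification factor per cycle, default 2.
#' @return List with `slope`, `intercept`, `r`, and per-fraction
#'   `measured` data frame (`null_fraction`, `deletion_proportion`).
#' @export
mixture_linearity <- function(series, efficiency = 2.0) {
  fr <- mixture_fractions(series)
  if (length(fr) < 3L) stop("need >= 3 mixture fractions")
  meas <- mixture_deletion_proportions(series, efficiency)
  fit <- stats::lm(deletion_proportion ~ null_fraction, data = meas)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(meas$null_fraction, meas$deletion_proportion),
       measured = meas)
}

mixture_fractions <- function(series) {
  stopifnot(all(c("null_fraction", "assay", "replicate", "ct") %in%
                  names(series)))
  fr <- sort(unique(series$null_fraction))
  if (!any(fr == 0)) stop("series must include the 0% (two-copy) control")
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  fr
}

# Mean deletion proportion per fraction, calibrated on the 0% mixture.
# A fraction whose target fails every replicate (pure zero-copy DNA) is
# a complete dropout: deletion proportion 1.
mixture_deletion_proportions <- function(series, efficiency = 2.0) {
  fr <- mixture_fractions(series)
  dct_of <- function(f) {
    sub <- series[series$null_fraction == f, , drop = FALSE]
    sub$sample_id <- "x"
    sample_delta_cts(sub, "x")$dct
  }
  cal <- mean(dct_of(0), na.rm = TRUE)
  dp <- vapply(fr, function(f) {
    d <- dct_of(f)
    if (all(is.na(d))) return(1)
    1 - relative_copy_number(mean(d, na.rm = TRUE), cal, efficiency)
  }, numeric(1))
  data.frame(null_fraction = fr, deletion_proportion = dp)
}

#' Detection limit of a spike-in dilution series
#'
#' Each nonzero null fraction is compared with the 0% (pure two-copy)
#' control by the paired two-sided t-test of [call_scnv()]. The
#' detection limit is the smallest fraction that is significant while
#' every larger fraction is also significant (the monotone rule guards
#' the "lowest significant dilution" definition against isolated false
#' positives).
#'
#' @inheritParams mixture_linearity
#' @param alpha Significance level, default 0.05.
#' @param test_space Passed to [call_scnv()].
#' @return List with `detection_limit` (a fraction, or `NA` when no
#'   fraction qualifies — not detected), `per_fraction` data frame
#'   (`null_fraction`, `p_value`, `significant`) and `alpha`.
#' @export
detection_limit <- function(series, alpha = 0.05, efficiency = 2.0,
                            test_space = c("dct", "rcn")) {
  test_space <- match.arg(test_space)
  fr <- mixture_fractions(series)
  dct_of <- function(f) {
    sub <- series[series$null_fraction == f, , drop = FALSE]
    sub$sample_id <- "x"
    d <- sample_delta_cts(sub, "x")$dct
    d[!is.na(d)]
  }
  cal_dct <- dct_of(0)
  cal <- mean(cal_dct)
  nonzero <- fr[fr > 0]
  pv <- vapply(nonzero, function(f) {
    d <- dct_of(f)
    values <- switch(test_space,
      dct = list(s = d, r = cal_dct),
      rcn = list(s = relative_copy_number(d, cal, efficiency),
                 r = relative_copy_number(cal_dct, cal, efficiency)))
    call_scnv(values$s, values$r, alpha, test_space)$p_value
  }, numeric(1))
  sig <- pv < alpha
  lod <- NA_real_
  # smallest fraction significant together with all larger fractions
  for (i in rev(seq_along(nonzero))) {
    if (!sig[i]) break
    lod <- nonzero[i]
  }
  list(detection_limit = lod,
       per_fraction = data.frame(null_fraction = nonzero, p_value = pv,
                                 significant = sig),
       alpha = alpha)
}

#' Controls policy check for a qPCR run
#'
#' A controlled run includes a pure two-copy control, a pure zero-copy
#' control, and the 20%/80% spike mixture. Their absence downgrades the
#' run status to `"uncontrolled"` rather than erroring.
#'
#' @param plate Plate data frame (see [quantify_samples()]).
#' @param control_ids Named list with entries `two_copy`, `zero_copy`,
#'   `mix20` giving the control sample_ids expected on the plate.
#' @return List with `status` (`"controlled"`/`"uncontrolled"`) and
#'   `missing` (character vector of absent control roles).
#' @export
check_controls <- function(plate,
                           control_ids = list(two_copy = "RKO_100",
                                              zero_copy = "A549_100",
                                              mix20 = "MIX_20")) {
  present <- vapply(control_ids, function(id) id %in% plate$sample_id,
                    logical(1))
  missing <- names(control_ids)[!present]
  list(status = if (length(missing)) "uncontrolled" else "controlled",
       missing = missing)
}
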