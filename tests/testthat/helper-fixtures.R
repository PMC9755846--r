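# Shared fixtures built in code.

# Report-rounding conventions: odds ratios to 2 decimals, percents to 1.
round_2 <- function(x) round_half_up(x, 2)
round_pct <- function(p) round_half_up(100 * p, 1)

# The 4-fragment toy cohort used across interval tests.
toy_cohort <- function() {
  rec <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    chrom = "chr9",
                    start = c(100, 200, 250, 700),
                    end = c(500, 600, 300, 900),
                    stringsAsFactors = FALSE)
  deletion_cohort(rec, genomic_interval("chr9", 1, 1000))
}

# Independent oracle: per-base deletion depth over a span, by counting.
brute_force_depth <- function(records, span_start, span_end) {
  pos <- span_start:span_end
  depth <- integer(length(pos))
  for (i in seq_len(nrow(records))) {
    hit <- pos >= records$start[i] & pos <= records$end[i]
    depth[hit] <- depth[hit] + 1L
  }
  depth
}

# Independent oracle for Fisher's two-sided p (point-probability rule):
# direct enumeration over all tables with the observed margins, with
# probabilities from binomial coefficients.
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Random small cohort on an integer span, for property tests.
random_cohort <- function(n, span_start = 1, span_end = 2000) {
  a <- sample(span_start:(span_end - 1), n, replace = TRUE)
  b <- pmin(span_end, a + sample(0:((span_end - span_start) %/% 2), n,
                                 replace = TRUE))
  rec <- data.frame(sample_id = sprintf("r%03d", seq_len(n)),
                    chrom = "chrT", start = a, end = b,
                    stringsAsFactors = FALSE)
  deletion_cohort(rec, genomic_interval("chrT", span_start, span_end))
}
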