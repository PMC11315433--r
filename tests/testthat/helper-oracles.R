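# Independent brute-force oracles: plain sum formulas, kept deliberately
# separate from the package's code paths (which go through base stats).

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pearson <- function(x, y) {
  mx <- oracle_mean(x); my <- oracle_mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- oracle_mean(d) / (oracle_sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

toy_cohort <- function() {
  as_cohort(tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    level = "C2-3",
    ap_diameter_mm = c(12, 11, 13),
    ipd_mm = c(24, 26, 22),
    measured_area_mm2 = c(250, 240, 230)
  ), provenance = "test:toy")
}

random_cohort <- function(n = 20, seed = 42) {
  set.seed(seed)
  lv <- sample(cervical_levels(), n, replace = TRUE)
  as_cohort(tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    level = lv,
    ap_diameter_mm = runif(n, 8, 16),
    ipd_mm = runif(n, 18, 30),
    measured_area_mm2 = runif(n, 180, 350)
  ), provenance = sprintf("test:random:seed=%d", seed))
}
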