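# Independent brute-force reference implementations used as oracles.
# Deliberately naive: explicit loops, no shared code with the package.

oracle_hm <- function(x) length(x) / sum(1 / x)

oracle_window_profile <- function(speeds, window) {
  nw <- length(speeds) - window + 1
  ws <- numeric(nw)
  for (i in seq_len(nw)) ws[i] <- oracle_hm(speeds[i:(i + window - 1)])
  ws
}

# Steps: gene speed, window profile, 5' below-gene run, outlier windows
# in the run, ramp end at last outlier window + window - 1.
oracle_detect_ramp <- function(speeds, window = 9, rule = "IQR", k = 1.5,
                               min_windows = 1) {
  n <- length(speeds)
  if (n < window) return(list(present = FALSE, ramp_end = 0L))
  gene <- oracle_hm(speeds)
  ws <- oracle_window_profile(speeds, window)
  if (rule == "IQR") {
    q <- stats::quantile(ws, c(0.25, 0.75), names = FALSE)
    fence <- q[1] - k * (q[2] - q[1])
  } else {
    fence <- mean(ws) - k * stats::sd(ws)
  }
  run <- 0
  for (i in seq_along(ws)) {
    if (ws[i] < gene) run <- i else break
  }
  qual <- integer(0)
  if (run >= 1) qual <- which(ws[seq_len(run)] < fence)
  if (length(qual) >= min_windows)
    list(present = TRUE, ramp_end = as.integer(max(qual) + window - 1))
  else
    list(present = FALSE, ramp_end = 0L)
}

# Naive chained nearest-previous pairing count.
oracle_pairing <- function(codons, window, adjacent = FALSE) {
  total <- 0
  for (j in seq_along(codons)) {
    prev <- which(codons[seq_len(j - 1)] == codons[j])
    if (length(prev) == 0) next
    d <- j - max(prev)
    if ((adjacent && d == 1) || (!adjacent && d < window)) total <- total + 1
  }
  total
}

# --- fixture builders -------------------------------------------------

uniform_table <- function(context_id = "uniform") {
  efficiency_table(context_id, stats::setNames(rep(1, 61), sense_codons()))
}

# table assigning `lo` to the codons in `slow`, `hi` to the rest
two_level_table <- function(slow, lo = 0.05, hi = 1, context_id = "two_level") {
  eff <- stats::setNames(rep(hi, 61), sense_codons())
  eff[slow] <- lo
  efficiency_table(context_id, eff)
}

random_table <- function(context_id = "rand", sdlog = 1) {
  vals <- exp(stats::rnorm(61, 0, sdlog))
  efficiency_table(context_id, stats::setNames(vals / max(vals), sense_codons()))
}

# random CDS of n codons incl. ATG start and TAA stop
random_cds <- function(n, id = "rnd") {
  body <- sample(sense_codons(), n - 2, replace = TRUE)
  coding_sequence(id, c("ATG", body, "TAA"))
}
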