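# Independent brute-force oracles used by the property tests. These are
# deliberately naive (loops, pairwise scans) and share no code with the
# implementation paths they check.

# Pairwise merge-until-fixed-point stitching.
oracle_stitch <- function(peaks, d) {
  regs <- peaks[order(peaks$chrom, peaks$start), c("chrom", "start", "end")]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(regs)) {
      same <- regs$chrom[i] == regs$chrom[i + 1L]
      gap <- regs$start[i + 1L] - regs$end[i]
      if (same && gap <= d) {
        regs$end[i] <- max(regs$end[i], regs$end[i + 1L])
        regs <- regs[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rownames(regs) <- NULL
  regs
}

# Exhaustive slope-scan super-enhancer cutoff: test every cut point in
# ascending order, return the set of signals above the first point
# whose forward rescaled slope exceeds 1.
oracle_super_set <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  if (length(unique(s)) == 1L) return(numeric(0))
  cut <- s[n]
  for (i in seq_len(n - 1L)) {
    y_i  <- (s[i] - s[1L]) / (s[n] - s[1L])
    y_i1 <- (s[i + 1L] - s[1L]) / (s[n] - s[1L])
    slope <- (y_i1 - y_i) * (n - 1L)
    if (slope > 1) { cut <- s[i]; break }
  }
  signals[signals > cut]
}

# Naive substring search for the 6-nt seed core in a UTR; returns all
# 1-based core start positions.
oracle_core_positions <- function(utr, core) {
  n <- nchar(utr)
  hits <- integer()
  for (p in seq_len(max(0L, n - 5L))) {
    if (substr(utr, p, p + 5L) == core) hits <- c(hits, p)
  }
  hits
}

# Quadratic containment check for AGO support.
oracle_ago_flags <- function(sites, intervals) {
  flags <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(intervals))) {
      if (sites$gene[i] == intervals$gene[j] &&
          intervals$start[j] <= sites$start[i] &&
          sites$end[i] <= intervals$end[j]) flags[i] <- TRUE
    }
  }
  flags
}

# Per-event nearest-center generation assignment in log space.
oracle_generation <- function(f, gen0, max_g) {
  centers <- gen0 / 2^(0:max_g)
  vapply(f, function(x) which.min(abs(log(x) - log(centers))) - 1L, integer(1L))
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_mirna_str <- function() random_rna_str(sample(18:26, 1L))
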