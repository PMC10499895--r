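# Independent brute-force oracles used to check the implementation paths.
# These deliberately use the dumbest possible algorithm.

# exhaustive scan over every possible integer window start
oracle_max_window <- function(positions, width) {
  best <- 0L
  for (s in min(positions):max(positions)) {
    n <- sum(positions >= s & positions <= s + width - 1L)
    if (n > best) best <- n
  }
  best
}

# quadratic pairwise single-linkage clustering
oracle_gap_clusters <- function(positions, max_gap) {
  p <- sort(positions)
  n <- length(p)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && abs(p[i] - p[j]) <= max_gap) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- as.integer(table(grp)[as.character(unique(grp[order(p)]))])
  sizes
}

# per-base boolean mask coverage
oracle_coverage <- function(track, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(track))) mask[track$start[i]:track$end[i]] <- TRUE
  sum(mask)
}

# closed-form normal equations for simple linear regression
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# naive quadratic substring scan
oracle_find_all <- function(seq, pat) {
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - nchar(pat) + 1L))
    if (substr(seq, i, i + nchar(pat) - 1L) == pat) hits <- c(hits, i)
  hits
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
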