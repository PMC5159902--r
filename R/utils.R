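# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonic-number constants used by the frequency-spectrum statistics:
# a1 = sum_{i=1}^{n-1} 1/i, a2 = sum 1/i^2 for a haploid sample of size n.
harmonic_a1 <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1))
}

harmonic_a2 <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1)^2)
}

# Overlap length of [s1,e1) with [s2,e2) (0-based half-open).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Merge adjacent/overlapping intervals in a data frame with chrom/start/end.
merge_intervals <- function(df, gap = 0) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (k in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$chrom[k] == out$chrom[last] && df$start[k] <= out$end[last] + gap) {
      out$end[last] <- max(out$end[last], df$end[k])
    } else {
      out <- rbind(out, df[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a single value in [0, 1]", name)
  invisible(x)
}
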