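# Read-depth CNV discovery: Poisson-homogeneous initial windows found by
# greedy extension under an exact two-sample Poisson rate test, two passes
# of significance-driven merging, copy-number estimation against the
# sample's modal depth, and retention of amplifications (CN > 1).

# Exact conditional test of equal Poisson rates: given totals x1, x2 over
# exposures t1, t2 bins, x1 | x1+x2 ~ Binomial(x1+x2, t1/(t1+t2)).
poisson_rate_test <- function(x1, t1, x2, t2) {
  n <- x1 + x2
  if (n == 0) return(1)
  stats::binom.test(x1, n, t1 / (t1 + t2))$p.value
}

join_threshold <- function(alpha, n_tests, adjust) {
  if (adjust == "bonferroni") alpha / max(1, n_tests) else alpha
}

#' Initial Poisson-homogeneous windows for one sample
#'
#' Greedy left-to-right extension: a bin joins the current window while the
#' exact Poisson rate test between the bin and the window is non-significant
#' at \code{alpha} (Bonferroni-adjusted per chromosome by default).
#' Windows never span chromosomes.
#'
#' @param track a \code{depth_track}.
#' @param sample sample id.
#' @param alpha significance level in (0, 1).
#' @param adjust "bonferroni" (per-chromosome) or "none".
#' @return data frame of windows with bin indices, bp coordinates, summed
#'   depth and bin count.
#' @export
segment_initial_windows <- function(track, sample, alpha = 0.01,
                                    adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  counts <- track$depth[, sample]
  out <- list()
  for (ch in unique(track$bins$chrom)) {
    idx <- which(track$bins$chrom == ch)
    if (length(idx) < 2)
      stop_config("need >= 2 bins per chromosome")
    thr <- join_threshold(alpha, length(idx) - 1, adjust)
    x <- counts[idx]
    starts <- c(); tot <- c(); nb <- c()
    cur_start <- 1L; cur_tot <- x[1]; cur_n <- 1L
    for (k in seq_along(x)[-1]) {
      p <- poisson_rate_test(x[k], 1, cur_tot, cur_n)
      if (p > thr) {
        cur_tot <- cur_tot + x[k]; cur_n <- cur_n + 1L
      } else {
        starts <- c(starts, cur_start); tot <- c(tot, cur_tot)
        nb <- c(nb, cur_n)
        cur_start <- k; cur_tot <- x[k]; cur_n <- 1L
      }
    }
    starts <- c(starts, cur_start); tot <- c(tot, cur_tot); nb <- c(nb, cur_n)
    ends <- starts + nb
    out[[ch]] <- data.frame(
      chrom = ch,
      bin_start = idx[starts], bin_end = idx[starts] + nb,
      start = track$bins$start[idx[starts]],
      end = track$bins$end[idx[ends - 1]],
      total = tot, n_bins = nb, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge adjacent windows with indistinguishable depth
#'
#' Runs exactly \code{passes} left-to-right merge sweeps; in each sweep
#' adjacent windows are pooled when the Poisson rate test between them is
#' non-significant at \code{alpha}.
#'
#' @param windows window data frame from [segment_initial_windows()].
#' @param alpha significance level.
#' @param passes number of merge sweeps (default 2).
#' @param adjust "bonferroni" or "none".
#' @return merged segment data frame with pooled depth.
#' @export
merge_windows <- function(windows, alpha = 0.01, passes = 2,
                          adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (any(order(windows$chrom, windows$start) != seq_len(nrow(windows))))
    stop_config("windows must be sorted by chromosome and start")
  for (p in seq_len(passes)) {
    out <- list()
    for (ch in unique(windows$chrom)) {
      w <- windows[windows$chrom == ch, , drop = FALSE]
      thr <- join_threshold(alpha, max(1, nrow(w) - 1), adjust)
      keep <- w[1, , drop = FALSE]
      for (k in seq_len(nrow(w))[-1]) {
        last <- nrow(keep)
        pv <- poisson_rate_test(w$total[k], w$n_bins[k],
                                keep$total[last], keep$n_bins[last])
        if (pv > thr) {
          keep$total[last] <- keep$total[last] + w$total[k]
          keep$n_bins[last] <- keep$n_bins[last] + w$n_bins[k]
          keep$end[last] <- w$end[k]
          keep$bin_end[last] <- w$bin_end[k]
        } else keep <- rbind(keep, w[k, , drop = FALSE])
      }
      out[[ch]] <- keep
    }
    windows <- do.call(rbind, out)
    rownames(windows) <- NULL
  }
  windows
}

# modal bin depth of a sample (diploid baseline resistant to large CNVs)
modal_depth <- function(counts) {
  tb <- table(round(counts))
  as.numeric(names(tb)[which.max(tb)])
}

#' Final depth segmentation for one sample
#'
#' @inheritParams segment_initial_windows
#' @param passes number of merge passes.
#' @return merged segment data frame.
#' @export
segment_sample <- function(track, sample, alpha = 0.01, passes = 2,
                           adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  merge_windows(segment_initial_windows(track, sample, alpha, adjust),
                alpha = alpha, passes = passes, adjust = adjust)
}

#' Call copy-number variants from depth segments
#'
#' Copy number of a segment is its mean depth divided by the sample's modal
#' bin depth (relative scale: 1 = reference state).  Only amplifications
#' are reported: segments whose rounded copy number is at least 2 are kept,
#' and adjacent retained segments with equal rounded copy number are
#' merged.  Depth-loss segments are the business of the PAV caller.
#'
#' @param track a \code{depth_track}.
#' @param samples sample ids (default: all in the track).
#' @param alpha segmentation significance level.
#' @param passes merge passes.
#' @param adjust multiple-testing adjustment for the segmentation tests.
#' @return data frame of calls: sample, chrom, start, end, cn (estimated),
#'   cn_round, n_bins.
#' @export
call_cnvs <- function(track, samples = track$samples, alpha = 0.01,
                      passes = 2, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  calls <- list()
  for (sm in samples) {
    if (mean(track$depth[, sm]) <= 0)
      stop_config("sample %s has zero genome-wide depth", sm)
    seg <- segment_sample(track, sm, alpha, passes, adjust)
    base <- modal_depth(track$depth[, sm])
    seg$cn <- (seg$total / seg$n_bins) / base
    seg$cn_round <- round(seg$cn)
    seg <- seg[seg$cn_round >= 2, , drop = FALSE]
    if (nrow(seg) > 1) {   # merge adjacent retained segments with equal CN
      out <- seg[1, , drop = FALSE]
      for (k in seq_len(nrow(seg))[-1]) {
        last <- nrow(out)
        if (seg$chrom[k] == out$chrom[last] &&
            seg$bin_start[k] == out$bin_end[last] &&
            seg$cn_round[k] == out$cn_round[last]) {
          out$end[last] <- seg$end[k]
          out$bin_end[last] <- seg$bin_end[k]
          out$total[last] <- out$total[last] + seg$total[k]
          out$n_bins[last] <- out$n_bins[last] + seg$n_bins[k]
          out$cn[last] <- (out$total[last] / out$n_bins[last]) / base
        } else out <- rbind(out, seg[k, , drop = FALSE])
      }
      seg <- out
    }
    if (nrow(seg))
      calls[[sm]] <- data.frame(sample = sm,
                                seg[, c("chrom", "start", "end", "cn",
                                        "cn_round", "n_bins")],
                                stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), cn = numeric(),
                      cn_round = integer(), n_bins = integer()))
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}
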