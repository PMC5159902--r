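# Windowed diversity statistics (pi, Watterson's theta, Tajima's D,
# Fu & Li's D*), Hudson FST / delta-pi differentiation scans and
# Tajima's-D region scans.
#
# Haploidization convention for a selfing diploid panel: a homozygote
# contributes two identical haplotypes, a heterozygote one of each; missing
# genotypes are removed site-wise (pairwise deletion).

#' Tile a genome into non-overlapping windows
#'
#' @param x a \code{genome_model} or a named vector of chromosome lengths.
#' @param size window size in bp (default 10 kb).
#' @return data frame with chrom, start, end (0-based half-open).
#' @export
make_windows <- function(x, size = 10000) {
  lens <- if (inherits(x, "genome_model"))
    stats::setNames(x$chromosomes$length, x$chromosomes$name)
  else x
  do.call(rbind, lapply(names(lens), function(ch) {
    st <- seq(0L, lens[[ch]] - 1L, by = size)
    data.frame(chrom = ch, start = st, end = pmin(st + size, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

# per-site alt-haplotype count x and non-missing haplotype count m
site_allele_counts <- function(panel, samples = NULL, snps_only = TRUE) {
  g <- panel$geno
  if (!is.null(samples)) {
    keep <- panel$samples$sample %in% samples
    if (!any(keep)) stop_config("no matching samples")
    g <- g[, keep, drop = FALSE]
  }
  sel <- if (snps_only) panel$sites$class == "SNP" else
    rep(TRUE, nrow(panel$sites))
  g <- g[sel, , drop = FALSE]
  data.frame(chrom = panel$sites$chrom[sel], pos = panel$sites$pos[sel],
             x = rowSums(g, na.rm = TRUE),
             m = 2L * rowSums(!is.na(g)),
             stringsAsFactors = FALSE)
}

# Tajima (1989) normalization constants for haploid sample size n
tajima_constants <- function(n) {
  a1 <- harmonic_a1(n); a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from summary quantities
#'
#' @param S number of segregating sites.
#' @param pi_total sum over sites of per-site pairwise diversity
#'   (i.e. pi x L, not per-bp).
#' @param n haploid sample size.
#' @return the D statistic, or NA when S = 0.
#' @export
tajima_d <- function(S, pi_total, n) {
  if (is.na(S) || S == 0 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fu & Li's D* (no outgroup, singleton-based)
#'
#' Uses the Simonsen-corrected variance terms; a singleton is a segregating
#' site at which either allele is carried by exactly one haplotype.
#'
#' @param S number of segregating sites.
#' @param eta_s number of singleton sites.
#' @param n haploid sample size.
#' @return the D* statistic, or NA when S = 0.
#' @export
fu_li_dstar <- function(S, eta_s, n) {
  if (is.na(S) || S == 0 || n < 4) return(NA_real_)
  a1 <- harmonic_a1(n); a2 <- harmonic_a2(n)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * (a1 + 1 / n) - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
  uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
  ((n / (n - 1)) * S - a1 * eta_s) / sqrt(uD * S + vD * S^2)
}

#' Windowed diversity statistics
#'
#' Computes, per window: accessible length L, window-averaged haploid sample
#' size n, segregating sites S, singleton count, per-site pi and Watterson's
#' theta_w = S / (a1 L), Tajima's D and Fu & Li's D*.  Only SNPs enter the
#' statistics.  pi uses the unbiased per-site estimator
#' x(m - x) / C(m, 2) with pairwise deletion of missing haplotypes.
#'
#' @param panel a \code{panel_genotypes}.
#' @param windows window data frame from [make_windows()].
#' @param samples optional sample subset (e.g. one market-type group).
#' @return data frame of class \code{window_stats}.
#' @export
window_diversity <- function(panel, windows, samples = NULL) {
  n_dip <- if (is.null(samples)) nrow(panel$samples) else
    sum(panel$samples$sample %in% samples)
  if (2 * n_dip < 4) stop_config("need a haploid sample size of at least 4")
  sc <- site_allele_counts(panel, samples)
  sc <- sc[sc$m >= 2, , drop = FALSE]
  widx <- assign_windows(sc$chrom, sc$pos, windows)
  poly <- sc$x > 0 & sc$x < sc$m
  single <- poly & pmin(sc$x, sc$m - sc$x) == 1
  pi_site <- ifelse(sc$m >= 2, sc$x * (sc$m - sc$x) / choose(sc$m, 2), 0)

  out <- windows
  out$L <- windows$end - windows$start
  nw <- nrow(windows)
  agg <- function(v, f) {
    z <- rep(0, nw)
    t <- tapply(v, widx, f)
    z[as.integer(names(t))] <- as.numeric(t)
    z
  }
  out$S <- agg(poly, sum)
  out$eta1 <- agg(single, sum)
  pi_tot <- agg(pi_site, sum)
  nbar <- rep(2 * n_dip, nw)
  has <- tabulate(widx, nbins = nw) > 0
  mt <- tapply(sc$m, widx, mean)
  nbar[as.integer(names(mt))] <- round(as.numeric(mt))
  out$n <- nbar
  out$pi <- pi_tot / out$L
  out$theta_w <- ifelse(out$S > 0,
                        out$S / (vapply(out$n, harmonic_a1, 1) * out$L), 0)
  out$tajima_d <- mapply(tajima_d, out$S, pi_tot, out$n)
  out$fuli_dstar <- mapply(fu_li_dstar, out$S, out$eta1, out$n)
  class(out) <- c("window_stats", "data.frame")
  out
}

# window index (or NA) for each site
assign_windows <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(windows$chrom)) {
    w <- which(windows$chrom == ch)
    s <- which(chrom == ch)
    if (!length(s)) next
    k <- findInterval(pos[s], windows$start[w])
    ok <- k >= 1 & pos[s] < windows$end[w][pmax(k, 1)]
    idx[s[ok]] <- w[k[ok]]
  }
  idx
}

#' Hudson's FST per window
#'
#' Per-site numerator and denominator of Hudson's estimator, combined as a
#' ratio of sums within each window (robust to unequal sample sizes).
#'
#' @param panel a \code{panel_genotypes}.
#' @param windows window data frame.
#' @param groupA,groupB character vectors of sample ids.
#' @return numeric vector of FST per window (NA where undefined).
#' @export
window_fst <- function(panel, windows, groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop_config("both groups need >= 2 samples")
  sa <- site_allele_counts(panel, groupA)
  sb <- site_allele_counts(panel, groupB)
  ok <- sa$m >= 2 & sb$m >= 2
  p1 <- sa$x / sa$m; p2 <- sb$x / sb$m
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (sa$m - 1) - p2 * (1 - p2) / (sb$m - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  widx <- assign_windows(sa$chrom, sa$pos, windows)
  nw <- nrow(windows)
  sum_by <- function(v) {
    z <- rep(0, nw)
    t <- tapply(ifelse(ok, v, 0), widx, sum)
    z[as.integer(names(t))] <- as.numeric(t)
    z
  }
  nsum <- sum_by(num); dsum <- sum_by(den)
  ifelse(dsum > 0, nsum / dsum, NA_real_)
}

#' Windowed diversity with group contrasts
#'
#' Convenience wrapper that adds Hudson FST and delta-pi (group A minus
#' group B, per site) to the [window_diversity()] table computed on the
#' full sample set.
#'
#' @inheritParams window_fst
#' @return a \code{window_stats} data frame with fst and dpi columns.
#' @export
diversity_stats <- function(panel, windows, groupA = NULL, groupB = NULL) {
  out <- window_diversity(panel, windows)
  if (!is.null(groupA) && !is.null(groupB)) {
    out$fst <- window_fst(panel, windows, groupA, groupB)
    piA <- window_diversity(panel, windows, samples = groupA)$pi
    piB <- window_diversity(panel, windows, samples = groupB)$pi
    out$dpi <- piA - piB
  }
  out
}

# merge adjacent selected windows into regions
windows_to_regions <- function(stats, sel) {
  s <- stats[sel, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  merge_intervals(s)
}

#' Differentiation scan (joint top FST and top |delta-pi| windows)
#'
#' Selects windows lying simultaneously in the top \code{top_fraction} of
#' the FST ranking and of the |delta-pi| ranking, and merges adjacent
#' selected windows into candidate selection regions.
#'
#' @param stats a \code{window_stats} table with fst and dpi columns.
#' @param top_fraction fraction of windows kept in each ranking
#'   (default 0.05).
#' @return data frame of regions with class "differentiation".
#' @export
differentiation_scan <- function(stats, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop_config("top_fraction must lie in (0, 1]")
  if (is.null(stats$fst) || is.null(stats$dpi))
    stop_config("stats must carry fst and dpi columns")
  ok <- !is.na(stats$fst) & !is.na(stats$dpi)
  k <- ceiling(top_fraction * sum(ok))
  thr_f <- sort(stats$fst[ok], decreasing = TRUE)[k]
  thr_d <- sort(abs(stats$dpi[ok]), decreasing = TRUE)[k]
  sel <- ok & stats$fst >= thr_f & abs(stats$dpi) >= thr_d
  reg <- windows_to_regions(stats, sel)
  reg$class <- rep("differentiation", nrow(reg))
  reg
}

#' Tajima's-D region scan for sweeps and balancing selection
#'
#' Flags the most extreme windows of the requested sign (direction-specific
#' empirical quantile), merges contiguous flagged windows into candidate
#' regions of span at least \code{min_span}, and (optionally) retains only
#' regions whose merged span is longer than expected under within-genome
#' permutation of the window flags (BH-adjusted permutation p-values).
#'
#' @param stats a \code{window_stats} table.
#' @param direction "negative" (sweep-like) or "positive" (balancing-like).
#' @param min_span minimum merged region span in bp (default 150 kb).
#' @param flag_quantile fraction of windows flagged as extreme (default 0.1).
#' @param null_method "permutation" (default) or "empirical-quantile" (no
#'   permutation gate).
#' @param alpha significance level applied to BH-adjusted permutation
#'   p-values.
#' @param n_perm number of permutations.
#' @return data frame of regions with span, window count, mean D and (for
#'   the permutation method) p and p_adj.
#' @export
tajima_region_scan <- function(stats, direction = c("negative", "positive"),
                               min_span = 150000, flag_quantile = 0.1,
                               null_method = c("permutation",
                                               "empirical-quantile"),
                               alpha = 0.05, n_perm = 200) {
  direction <- match.arg(direction)
  null_method <- match.arg(null_method)
  d <- stats$tajima_d
  if (all(is.na(d))) stop_config("Tajima's D is undefined in every window")
  ok <- !is.na(d)
  thr <- stats::quantile(d[ok],
                         if (direction == "negative") flag_quantile
                         else 1 - flag_quantile)
  flag <- ok & (if (direction == "negative") d <= thr else d >= thr)

  region_runs <- function(flag) {
    runs <- list()
    cur <- NULL
    for (i in seq_len(nrow(stats))) {
      contiguous <- !is.null(cur) &&
        stats$chrom[i] == cur$chrom && stats$start[i] == cur$end
      if (flag[i]) {
        if (contiguous) {
          cur$end <- stats$end[i]; cur$n_windows <- cur$n_windows + 1L
          cur$sum_d <- cur$sum_d + d[i]
        } else {
          if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
          cur <- list(chrom = stats$chrom[i], start = stats$start[i],
                      end = stats$end[i], n_windows = 1L, sum_d = d[i])
        }
      } else if (!is.null(cur)) {
        runs[[length(runs) + 1]] <- cur; cur <- NULL
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
    runs
  }
  runs <- region_runs(flag)
  if (!length(runs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      n_windows = integer(), mean_d = numeric(),
                      class = character()))
  reg <- do.call(rbind, lapply(runs, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               span = r$end - r$start, n_windows = r$n_windows,
               mean_d = r$sum_d / r$n_windows, stringsAsFactors = FALSE)))
  reg <- reg[reg$span >= min_span, , drop = FALSE]
  if (nrow(reg) == 0 || null_method == "empirical-quantile") {
    rownames(reg) <- NULL
    reg$class <- rep(if (direction == "negative") "sweep" else "balancing",
                     nrow(reg))
    return(reg)
  }
  # permutation null for the maximum merged-run span
  null_max <- vapply(seq_len(n_perm), function(b) {
    rb <- region_runs(sample(flag))
    if (!length(rb)) 0 else max(vapply(rb, function(r) r$end - r$start, 1))
  }, numeric(1))
  reg$p <- vapply(reg$span, function(sp)
    (1 + sum(null_max >= sp)) / (n_perm + 1), numeric(1))
  reg$p_adj <- stats::p.adjust(reg$p, method = "BH")
  reg <- reg[reg$p_adj <= alpha, , drop = FALSE]
  rownames(reg) <- NULL
  reg$class <- rep(if (direction == "negative") "sweep" else "balancing",
                   nrow(reg))
  reg
}
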