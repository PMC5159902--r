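# Pairwise linkage disequilibrium from unphased, mostly-homozygous
# genotypes (two-locus EM for the double-heterozygote ambiguity), LD-decay
# profiles with a monotone-smoothed half-maximum decay distance, and
# Gabriel-style haplotype blocks from D-prime confidence intervals.

# Haplotype bookkeeping for a site pair from dosage vectors: unambiguous
# haplotype counts c11, c10, c01, c00 (allele 1 = alt) and the number of
# double heterozygotes dh.  Uses only samples non-missing at both sites.
pair_hap_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  a <- g1[ok]; b <- g2[ok]
  N <- function(u, v) sum(a == u & b == v)
  list(c11 = 2 * N(2, 2) + N(2, 1) + N(1, 2),
       c10 = 2 * N(2, 0) + N(2, 1) + N(1, 0),
       c01 = 2 * N(0, 2) + N(1, 2) + N(0, 1),
       c00 = 2 * N(0, 0) + N(0, 1) + N(1, 0),
       dh = N(1, 1), n = sum(ok))
}

# EM for haplotype frequencies given the counts; returns p11,p10,p01,p00
hap_freq_em <- function(cnt, max_iter = 100, tol = 1e-12) {
  tot <- cnt$c11 + cnt$c10 + cnt$c01 + cnt$c00 + 2 * cnt$dh
  if (tot == 0) return(NULL)
  w <- 0.5
  for (it in seq_len(max_iter)) {
    h11 <- cnt$c11 + cnt$dh * w; h00 <- cnt$c00 + cnt$dh * w
    h10 <- cnt$c10 + cnt$dh * (1 - w); h01 <- cnt$c01 + cnt$dh * (1 - w)
    p <- c(h11, h10, h01, h00) / tot
    if (cnt$dh == 0) break
    num <- p[1] * p[4]
    den <- num + p[2] * p[3]
    w_new <- if (den > 0) num / den else 0.5
    if (abs(w_new - w) < tol) { w <- w_new; break }
    w <- w_new
  }
  h11 <- cnt$c11 + cnt$dh * w; h00 <- cnt$c00 + cnt$dh * w
  h10 <- cnt$c10 + cnt$dh * (1 - w); h01 <- cnt$c01 + cnt$dh * (1 - w)
  c(h11, h10, h01, h00) / tot
}

ld_from_freqs <- function(p) {
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(c(r2 = NA_real_, dprime = NA_real_, D = NA_real_))
  D <- p[1] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else NA_real_
  c(r2 = r2, dprime = dprime, D = D)
}

#' LD between one pair of sites
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) at the two sites.
#' @return named vector with r2, dprime and D (NA when either site is
#'   monomorphic among the shared non-missing samples).
#' @export
ld_pair <- function(g1, g2) {
  p <- hap_freq_em(pair_hap_counts(g1, g2))
  if (is.null(p)) return(c(r2 = NA_real_, dprime = NA_real_, D = NA_real_))
  ld_from_freqs(p)
}

#' Pairwise LD within a distance cutoff
#'
#' Computes r-squared and D-prime for every SNP pair on the same chromosome
#' separated by at most \code{max_distance}, from haplotype frequencies
#' estimated by composite counting with a two-locus EM for double
#' heterozygotes.
#'
#' @param panel a \code{panel_genotypes}.
#' @param max_distance maximum pair separation in bp (default 500 kb).
#' @param samples optional sample subset (e.g. one market-type group).
#' @return data frame: chrom, pos1, pos2, dist, r2, dprime.
#' @export
pairwise_ld <- function(panel, max_distance = 500000, samples = NULL) {
  g <- panel$geno[panel$sites$class == "SNP", , drop = FALSE]
  s <- panel$sites[panel$sites$class == "SNP", , drop = FALSE]
  if (!is.null(samples)) {
    keep <- panel$samples$sample %in% samples
    g <- g[, keep, drop = FALSE]
  }
  out <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    pos <- s$pos[idx]
    for (a in seq_along(idx)) {
      js <- idx[pos > pos[a] & pos <= pos[a] + max_distance]
      if (!length(js)) next
      i <- idx[a]
      vals <- vapply(js, function(j) ld_pair(g[i, ], g[j, ]), numeric(3))
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, pos1 = s$pos[i], pos2 = s$pos[js],
        dist = s$pos[js] - s$pos[i],
        r2 = vals[1, ], dprime = vals[2, ], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), dist = integer(), r2 = numeric(),
                      dprime = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LD-decay profile
#'
#' Mean r-squared per distance bin, a decreasing-monotone smooth (isotonic
#' regression), and the decay distance: the midpoint of the first bin at
#' which the smoothed curve falls below half of its maximum.
#'
#' @param pairs output of [pairwise_ld()].
#' @param bin_width distance bin width in bp (default 10 kb).
#' @param group optional label attached to the profile.
#' @return list with \code{profile} (data frame) and
#'   \code{decay_distance} (bp).
#' @export
ld_decay <- function(pairs, bin_width = 10000, group = NA) {
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  if (nrow(pairs) == 0) stop_config("no informative pairs")
  b <- pairs$dist %/% bin_width
  mean_r2 <- tapply(pairs$r2, b, mean)
  bs <- as.integer(names(mean_r2))
  profile <- data.frame(bin_start = bs * bin_width,
                        bin_end = (bs + 1) * bin_width,
                        mid = (bs + 0.5) * bin_width,
                        n_pairs = as.integer(table(b)),
                        mean_r2 = as.numeric(mean_r2))
  sm <- if (nrow(profile) > 1)
    -stats::isoreg(profile$mid, -profile$mean_r2)$yf
  else profile$mean_r2
  profile$smoothed <- sm
  cross <- which(sm < max(sm) / 2)
  decay <- if (length(cross)) profile$mid[cross[1]]
           else profile$mid[nrow(profile)]
  list(profile = profile, decay_distance = decay, group = group)
}

# 90% likelihood interval for |D'| on a grid, from the haplotype-level
# likelihood (unambiguous haplotype counts + double-het mixture term).
dprime_ci <- function(cnt, level = 0.90, grid_n = 101) {
  tot <- cnt$c11 + cnt$c10 + cnt$c01 + cnt$c00 + 2 * cnt$dh
  if (tot == 0) return(c(NA_real_, NA_real_))
  p <- hap_freq_em(cnt)
  if (is.null(p)) return(c(NA_real_, NA_real_))
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(c(NA_real_, NA_real_))
  D <- p[1] - pA * pB
  sgn <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp_grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(dp_grid, function(dp) {
    Dg <- sgn * dp * dmax
    q <- c(pA * pB + Dg, pA * (1 - pB) - Dg, (1 - pA) * pB - Dg,
           (1 - pA) * (1 - pB) + Dg)
    q <- pmax(q, 1e-12)
    cnt$c11 * log(q[1]) + cnt$c10 * log(q[2]) + cnt$c01 * log(q[3]) +
      cnt$c00 * log(q[4]) + cnt$dh * log(q[1] * q[4] + q[2] * q[3])
  }, numeric(1))
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  tail_p <- (1 - level) / 2
  lo <- dp_grid[which(cum >= tail_p)[1]]
  hi <- dp_grid[which(cum >= 1 - tail_p)[1]]
  c(lo, hi)
}

#' Haplotype blocks by the D-prime confidence-interval method
#'
#' A pair is in strong LD when its 90\% |D'| interval lies above 0.70 with
#' upper bound at least 0.98, and shows strong recombination when the upper
#' bound is below 0.90; other pairs are uninformative.  A candidate block
#' is a SNP run whose outermost pair is in strong LD and in which at least
#' 95\% of informative pairs are in strong LD.  Blocks are accepted
#' greedily, longest span first, without overlap.
#'
#' @param panel a \code{panel_genotypes}.
#' @param samples optional sample subset.
#' @param max_span maximum block span in bp (default 100 kb).
#' @param strong_low,strong_high,recomb_high CI thresholds (Gabriel
#'   defaults).
#' @param min_strong_frac minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @return data frame of non-overlapping blocks sorted by position:
#'   chrom, start, end, span, n_snps.
#' @export
haplotype_blocks <- function(panel, samples = NULL, max_span = 100000,
                             strong_low = 0.70, strong_high = 0.98,
                             recomb_high = 0.90, min_strong_frac = 0.95) {
  g <- panel$geno[panel$sites$class == "SNP", , drop = FALSE]
  s <- panel$sites[panel$sites$class == "SNP", , drop = FALSE]
  if (!is.null(samples)) {
    keep <- panel$samples$sample %in% samples
    g <- g[, keep, drop = FALSE]
  }
  if (nrow(s) < 2)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      n_snps = integer()))
  blocks <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    pos <- s$pos[idx]
    nI <- length(idx)
    if (nI < 2) next
    # classify pairs within the span cutoff: 1 strong LD, -1 recomb, 0 other
    cls <- matrix(0L, nI, nI)
    for (a in seq_len(nI - 1)) for (b in (a + 1):nI) {
      if (pos[b] - pos[a] > max_span) break
      ci <- dprime_ci(pair_hap_counts(g[idx[a], ], g[idx[b], ]))
      if (any(is.na(ci))) next
      if (ci[1] >= strong_low && ci[2] >= strong_high) cls[a, b] <- 1L
      else if (ci[2] < recomb_high) cls[a, b] <- -1L
    }
    # candidate blocks: outermost pair strong, >=95% informative pairs strong
    cand <- list()
    for (a in seq_len(nI - 1)) for (b in (a + 1):nI) {
      if (pos[b] - pos[a] > max_span) break
      if (cls[a, b] != 1L) next
      sub <- cls[a:b, a:b]
      ns <- sum(sub == 1L); nr <- sum(sub == -1L)
      if (ns + nr == 0 || ns / (ns + nr) < min_strong_frac) next
      cand[[length(cand) + 1]] <- c(a = a, b = b, span = pos[b] - pos[a])
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "span"]), , drop = FALSE]
    used <- rep(FALSE, nI)
    for (k in seq_len(nrow(cand))) {
      rng <- cand[k, "a"]:cand[k, "b"]
      if (any(used[rng])) next
      used[rng] <- TRUE
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = ch, start = pos[cand[k, "a"]], end = pos[cand[k, "b"]],
        span = cand[k, "span"], n_snps = length(rng),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      n_snps = integer()))
  res <- do.call(rbind, blocks)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}
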