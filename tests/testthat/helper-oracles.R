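# Independent straight-from-formula oracles, written with explicit loops
# and no reuse of package internals.  These define the expected values for
# the statistic-equivalence tests.

# expand a dosage matrix (sites x samples) into haplotypes (sites x 2n);
# a heterozygote contributes one ref and one alt haplotype
oracle_haplotypes <- function(geno) {
  n <- ncol(geno)
  H <- matrix(NA_integer_, nrow(geno), 2 * n)
  for (j in seq_len(n)) {
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, j]
      if (is.na(g)) next
      H[i, 2 * j - 1] <- if (g == 2) 1L else 0L
      H[i, 2 * j] <- if (g >= 1) 1L else 0L
    }
  }
  H
}

# pi, theta_w, Tajima's D, Fu & Li's D* over a window of length L
oracle_window_stats <- function(geno, L) {
  H <- oracle_haplotypes(geno)
  pi_total <- 0; S <- 0; eta1 <- 0; msum <- 0; nsites <- 0
  for (i in seq_len(nrow(H))) {
    h <- H[i, !is.na(H[i, ])]
    m <- length(h)
    if (m < 2) next
    nsites <- nsites + 1; msum <- msum + m
    diffs <- 0; pairs <- 0
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      pairs <- pairs + 1
      if (h[a] != h[b]) diffs <- diffs + 1
    }
    pi_total <- pi_total + diffs / pairs
    x <- sum(h)
    if (x > 0 && x < m) {
      S <- S + 1
      if (min(x, m - x) == 1) eta1 <- eta1 + 1
    }
  }
  n <- if (nsites > 0) round(msum / nsites) else 0
  a1 <- sum(1 / seq_len(max(n - 1, 1)))
  a2 <- sum(1 / seq_len(max(n - 1, 1))^2)
  theta_w <- if (S > 0) S / (a1 * L) else 0
  tajd <- NA_real_
  if (S > 0 && n >= 4) {
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    tajd <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  dstar <- NA_real_
  if (S > 0 && n >= 4) {
    cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
    dn <- cn + (n - 2) / (n - 1)^2 +
      (2 / (n - 1)) * (1.5 - (2 * (a1 + 1 / n) - 3) / (n - 2) - 1 / n)
    vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
             2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
    uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
    dstar <- ((n / (n - 1)) * S - a1 * eta1) / sqrt(uD * S + vD * S^2)
  }
  list(pi = pi_total / L, theta_w = theta_w, S = S, eta1 = eta1, n = n,
       tajima_d = tajd, fuli_dstar = dstar)
}

# Hudson FST, ratio of per-site sums
oracle_fst <- function(gA, gB) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(gA))) {
    ha <- oracle_haplotypes(gA[i, , drop = FALSE])
    hb <- oracle_haplotypes(gB[i, , drop = FALSE])
    ha <- ha[!is.na(ha)]; hb <- hb[!is.na(hb)]
    n1 <- length(ha); n2 <- length(hb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(ha) / n1; p2 <- sum(hb) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den > 0) num / den else NA_real_
}

# r2 and D' by direct haplotype counting; only valid without double
# heterozygotes (phase then unambiguous)
oracle_ld <- function(g1, g2) {
  stopifnot(!any(g1 == 1 & g2 == 1, na.rm = TRUE))
  n11 <- 0; n10 <- 0; n01 <- 0; n00 <- 0
  for (j in seq_along(g1)) {
    a <- g1[j]; b <- g2[j]
    if (is.na(a) || is.na(b)) next
    # enumerate the two haplotypes of this individual
    ha <- c(if (a == 2) c(1, 1) else if (a == 1) c(1, 0) else c(0, 0))
    hb <- c(if (b == 2) c(1, 1) else if (b == 1) c(1, 0) else c(0, 0))
    # at most one locus is heterozygous, so pairing order is irrelevant
    # except that the alt allele of the het must pair with both orders
    # consistently; enumerate directly:
    combo <- rbind(c(ha[1], hb[1]), c(ha[2], hb[2]))
    for (r in 1:2) {
      if (combo[r, 1] == 1 && combo[r, 2] == 1) n11 <- n11 + 1
      else if (combo[r, 1] == 1) n10 <- n10 + 1
      else if (combo[r, 2] == 1) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  tot <- n11 + n10 + n01 + n00
  if (tot == 0) return(c(r2 = NA, dprime = NA))
  p11 <- n11 / tot
  pA <- (n11 + n10) / tot; pB <- (n11 + n01) / tot
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(c(r2 = NA, dprime = NA))
  D <- p11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = r2, dprime = if (dmax > 0) abs(D) / dmax else NA)
}

# allele-sharing distance by per-pair per-site loops
oracle_distance <- function(geno) {
  n <- ncol(geno)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- 0; cnt <- 0
    for (s in seq_len(nrow(geno))) {
      a <- geno[s, i]; b <- geno[s, j]
      if (is.na(a) || is.na(b)) next
      cnt <- cnt + 1
      tot <- tot + (1 - abs(a - b) / 2)
    }
    D[i, j] <- 1 - tot / cnt
  }
  D
}
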