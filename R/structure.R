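# Population structure: allele-sharing distances, neighbor-joining tree,
# Patterson-scaled PCA with Tracy-Widom significance, and admixture
# proportions by EM on the binomial admixture likelihood.

#' Allele-sharing distance matrix
#'
#' d(i, j) = 1 - IBS(i, j), where IBS is the mean (over sites non-missing
#' in both samples) shared-allele fraction: identical genotypes share 1,
#' opposite homozygotes 0, and any pair involving one heterozygote 0.5.
#'
#' @param panel a \code{panel_genotypes}.
#' @return symmetric matrix with zero diagonal, labelled by sample id.
#' @export
distance_matrix <- function(panel) {
  n <- nrow(panel$samples)
  if (n < 2) stop_config("need >= 2 samples")
  g <- panel$geno
  D <- matrix(0, n, n,
              dimnames = list(panel$samples$sample, panel$samples$sample))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    if (!any(ok))
      stop_config("samples %s and %s share no non-missing sites",
                  panel$samples$sample[i], panel$samples$sample[j])
    ibs <- mean(1 - abs(g[ok, i] - g[ok, j]) / 2)
    D[i, j] <- D[j, i] <- 1 - ibs
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Negative branch
#' lengths are clamped to zero with the length transferred to the adjacent
#' branch of the joined pair, preserving their summed distance.
#'
#' @param D symmetric distance matrix with labels.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop_config("distance matrix must be symmetric")
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop_config("need >= 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  nwk <- labels   # newick substring per active node
  act <- seq_len(n)
  while (length(act) > 3) {
    r <- length(act)
    d <- D[act, act]
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[act[i]], li,
                       nwk[act[j]], lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    # attach the new node in place of i; drop j
    ai <- act[i]; aj <- act[j]
    D[ai, act] <- du; D[act, ai] <- du; D[ai, ai] <- 0
    nwk[ai] <- new_nwk
    act <- act[act != aj]
  }
  d <- D[act, act]
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l <- pmax(c(l1, l2, l3), 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[act[1]], l[1], nwk[act[2]], l[2], nwk[act[3]], l[3])
  ape::read.tree(text = txt)
}

# Tracy-Widom (beta = 1) upper-tail probability, via the shifted-gamma
# moment-matching approximation of Chiani (2014).
ptw1_upper <- function(x) {
  k <- 46.44604884387
  theta <- 0.18605402228279955
  shift <- 9.848007781128567
  stats::pgamma(x + shift, shape = k, scale = theta, lower.tail = FALSE)
}

# tabulated TW1 quantiles for the conventional significance levels
tw1_quantiles <- c(`0.05` = 0.9793, `0.01` = 2.0234)

#' PCA of the genotype matrix with Tracy-Widom significance
#'
#' Sites are centered and scaled by sqrt(p(1 - p)) (Patterson
#' normalization; missing genotypes are mean-imputed), the sample
#' covariance is eigendecomposed, and each leading eigenvalue is tested
#' against the Tracy-Widom law using the effective-marker correction
#' estimated from the eigenvalue dispersion.
#'
#' @param panel a \code{panel_genotypes}.
#' @return object of class \code{panel_pca}: eigenvalues, eigenvectors
#'   (samples x axes), Tracy-Widom statistics and p-values.
#' @export
pca_genotypes <- function(panel) {
  if (nrow(panel$samples) < 3) stop_config("need >= 3 samples")
  g <- panel$geno[panel$sites$class == "SNP", , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop_config("need >= 2 polymorphic sites")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  M <- (g - mu) / sqrt(p * (1 - p))
  M[is.na(M)] <- 0
  m <- nrow(M); n <- ncol(M)
  C <- crossprod(M) / m
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  L <- n - 1    # rank after centering
  lam <- vals[seq_len(L)]
  tw <- pv <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    lam_i <- lam[i:L]
    mi <- length(lam_i)
    if (mi < 2 || sum(lam_i) <= 0) break
    s1 <- sum(lam_i); s2 <- sum(lam_i^2)
    n_eff <- ((mi + 1) * s1^2) / (mi * s2 - s1^2)
    if (!is.finite(n_eff) || n_eff <= 1) break
    l <- mi * lam_i[1] / s1
    mu_tw <- (sqrt(n_eff - 1) + sqrt(mi))^2 / n_eff
    sd_tw <- ((sqrt(n_eff - 1) + sqrt(mi)) / n_eff) *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(mi))^(1 / 3)
    tw[i] <- (l - mu_tw) / sd_tw
    pv[i] <- ptw1_upper(tw[i])
  }
  structure(list(values = vals,
                 vectors = e$vectors,
                 twstats = tw, pvalues = pv, n_sites = m,
                 samples = panel$samples$sample),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  k <- min(5, length(x$values))
  cat(sprintf("panel_pca: %d sites, %d samples\n", x$n_sites,
              length(x$samples)))
  cat("leading eigenvalues:", signif(x$values[1:k], 4), "\n")
  cat("Tracy-Widom p:", signif(x$pvalues[1:k], 3), "\n")
  invisible(x)
}

#' Admixture proportions by EM
#'
#' Maximum-likelihood estimation of ancestry fractions Q (samples x K) and
#' ancestral allele frequencies F (K x sites) under the binomial admixture
#' model g_ij ~ Binomial(2, sum_k q_ik f_kj), by the standard EM updates.
#' The log-likelihood is non-decreasing at every iteration; multiple seeded
#' restarts keep the best optimum.
#'
#' @param panel a \code{panel_genotypes}.
#' @param K number of ancestral clusters (1 <= K <= n samples).
#' @param max_iter iteration cap (default 10000).
#' @param tol stop when the log-likelihood gain drops below this.
#' @param restarts number of random restarts (default 5).
#' @param seed RNG seed for the restarts.
#' @param min_maf minor-allele-frequency floor for the SNPs used (default
#'   0.05): rare alleles carry almost no ancestry information and only
#'   slow the EM down.
#' @return object of class \code{admixture_fit} with Q, F, loglik,
#'   loglik_trace and iterations.
#' @export
admixture_em <- function(panel, K, max_iter = 10000, tol = 1e-6,
                         restarts = 5, seed = 1, min_maf = 0.05) {
  snp <- panel$sites$class == "SNP"
  if (min_maf > 0) {
    x <- rowSums(panel$geno, na.rm = TRUE)
    m <- 2 * rowSums(!is.na(panel$geno))
    maf <- ifelse(m > 0, pmin(x / m, 1 - x / m), 0)
    snp <- snp & maf >= min_maf
  }
  if (!any(snp)) stop_config("no SNPs left after the MAF filter")
  G <- t(panel$geno[snp, , drop = FALSE])  # n x S
  n <- nrow(G); S <- ncol(G)
  if (K < 1) stop_config("K must be >= 1")
  if (K > n) stop_config("K cannot exceed the number of samples")
  W <- !is.na(G)
  G0 <- ifelse(W, G, 0)
  H0 <- ifelse(W, 2 - G, 0)
  Msites <- rowSums(W)

  loglik <- function(Q, F) {
    P <- pmin(pmax(Q %*% F, 1e-12), 1 - 1e-12)
    sum(G0 * log(P) + H0 * log1p(-P))
  }
  if (K == 1) {
    F <- matrix(colSums(G0) / (2 * colSums(W)), 1, S)
    Q <- matrix(1, n, 1)
    ll <- loglik(Q, F)
    fit <- list(Q = Q, F = F, loglik = ll, loglik_trace = ll,
                iterations = 0L, K = 1L)
  } else {
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
      Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
      F <- matrix(stats::runif(K * S, 0.05, 0.95), K, S)
      trace <- numeric(0)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        P <- pmin(pmax(Q %*% F, 1e-12), 1 - 1e-12)
        A <- G0 / P
        B <- H0 / (1 - P)
        Q <- Q * (A %*% t(F) + B %*% t(1 - F)) / (2 * Msites)
        Q <- Q / rowSums(Q)   # guard accumulation of rounding error
        num <- F * (t(Q) %*% A)
        den <- num + (1 - F) * (t(Q) %*% B)
        F <- ifelse(den > 0, num / den, F)
        F <- pmin(pmax(F, 1e-6), 1 - 1e-6)
        ll <- loglik(Q, F)
        trace <- c(trace, ll)
        if (is.finite(ll_old) && ll - ll_old < tol) break
        ll_old <- ll
      }
      if (is.null(best) || trace[length(trace)] > best$loglik)
        best <- list(Q = Q, F = F, loglik = trace[length(trace)],
                     loglik_trace = trace, iterations = length(trace),
                     K = as.integer(K))
    }
    fit <- best
  }
  rownames(fit$Q) <- panel$samples$sample
  class(fit) <- "admixture_fit"
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d samples, logLik %.2f (%d iter)\n",
              x$K, nrow(x$Q), x$loglik, x$iterations))
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$Q) + length(object$F),
            class = "logLik")
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' Align cluster labels of an estimated Q to a reference
#'
#' Searches the K! column permutations for the one minimizing mean |Q - Q0|.
#'
#' @param Q estimated ancestry matrix.
#' @param Q0 reference ancestry matrix of the same shape.
#' @return list with the permuted Q, the permutation and the mean absolute
#'   error.
#' @export
align_q <- function(Q, Q0) {
  K <- ncol(Q)
  perms <- permutations_of(seq_len(K))
  best <- NULL
  for (p in perms) {
    err <- mean(abs(Q[, p, drop = FALSE] - Q0))
    if (is.null(best) || err < best$mae)
      best <- list(Q = Q[, p, drop = FALSE], perm = p, mae = err)
  }
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}
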