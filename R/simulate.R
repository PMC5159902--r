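# Synthetic variety-panel generator: toy genome with CDS-bearing gene models,
# a structured, mostly-selfing diploid panel, per-sample depth tracks with
# planted CNV/PAV events, and the truth ledger used to validate every
# downstream stage.

#' Configuration for the synthetic variety panel
#'
#' Collects every tunable of the generator: genome geometry, panel layout
#' (market type desi/kabuli crossed with release periods RP1/RP2/RP3),
#' population-genetic parameters and the planted structural/selective events.
#' All coordinates are 0-based half-open; they are converted to 1-based only
#' when written to VCF/GFF3.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp),
#'   each at least 10 kb.
#' @param cds_fraction fraction of the genome covered by CDS (default 0.25).
#' @param samples_per_group number of varieties per market-type x
#'   release-period cell (6 cells, so the default 4 gives a 24-sample panel).
#' @param n_samples optional exact panel size, overriding
#'   \code{samples_per_group} (cells are filled round-robin).
#' @param n_subpops number of ancestral subpopulations (default 3).
#' @param theta scaled mutation rate per bp (pairwise diversity scale).
#' @param divergence Balding--Nichols F governing allele-frequency drift of
#'   each subpopulation away from the ancestral frequency.
#' @param admix_alpha symmetric Dirichlet concentration for per-sample
#'   ancestry proportions; small values give near-pure assignments.
#' @param selfing probability that a heterozygous genotype is collapsed to a
#'   random homozygote (selfing species: default 0.98).
#' @param missing_rate per-genotype missingness probability.
#' @param mean_depth genome-wide mean sequencing depth per sample.
#' @param depth_bin width (bp) of the depth-track bins (default 1 kb).
#' @param indel_fraction fraction of variant sites simulated as 1--10 bp
#'   insertions/deletions rather than SNPs.
#' @param linkage NULL for the independent-site model (exact neutral
#'   spectrum; no LD beyond structure), or a list
#'   \code{list(n_founders, recomb_rate, hotspots)} activating the
#'   founder-mosaic model: haplotypes are mosaics of per-subpopulation
#'   founder haplotypes with switch intensity \code{recomb_rate} per bp
#'   (plus any hotspot extra rates), which creates LD decaying with
#'   physical distance.
#' @param sweeps data frame (chrom, start, end, factor, subpop) of planted
#'   low-diversity regions; \code{factor} multiplies site density and minor
#'   allele frequencies down; \code{subpop = NA} applies panel-wide.
#' @param balancing data frame (chrom, start, end, strength) of regions whose
#'   allele frequencies are pulled toward 0.5 with the given strength.
#' @param cnv_events data frame (sample, chrom, start, end, copy) of planted
#'   copy-number events on the relative scale where 1 = reference state.
#' @param pav_events data frame (sample, chrom, start, end, state, class) of
#'   planted presence/absence events; \code{class} is "deletion" or
#'   "insertion"; absence is a depth multiplier of 0.05.
#' @param seed integer seed; all output is deterministic given the seed.
#' @return an object of class \code{panel_config}.
#' @export
panel_config <- function(chrom_lengths = c(Ca1 = 200000, Ca2 = 200000),
                         cds_fraction = 0.25,
                         samples_per_group = 4,
                         n_samples = NULL,
                         n_subpops = 3,
                         theta = 0.002,
                         divergence = 0.1,
                         admix_alpha = 0.2,
                         selfing = 0.98,
                         missing_rate = 0.03,
                         mean_depth = 10,
                         depth_bin = 1000,
                         indel_fraction = 0.1,
                         linkage = NULL,
                         sweeps = NULL,
                         balancing = NULL,
                         cnv_events = NULL,
                         pav_events = NULL,
                         seed = 1) {
  if (length(chrom_lengths) < 1 || any(chrom_lengths < 10000))
    stop_config("need >= 1 chromosome, each >= 10 kb")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("Ca", seq_along(chrom_lengths))
  if (cds_fraction < 0 || cds_fraction > 1)
    stop_config("cds_fraction must lie in [0, 1]")
  if (theta <= 0) stop_config("theta must be > 0")
  if (mean_depth <= 0) stop_config("mean_depth must be > 0")
  if (n_subpops < 1) stop_config("n_subpops must be >= 1")
  check_prob(selfing, "selfing")
  check_prob(missing_rate, "missing_rate")
  check_prob(divergence, "divergence")
  check_prob(indel_fraction, "indel_fraction")
  if (!is.null(linkage)) {
    if (is.null(linkage$n_founders) || linkage$n_founders < 2 ||
        is.null(linkage$recomb_rate) || linkage$recomb_rate < 0)
      stop_config("linkage needs n_founders >= 2 and recomb_rate >= 0")
  }
  cfg <- list(chrom_lengths = chrom_lengths, cds_fraction = cds_fraction,
              samples_per_group = samples_per_group, n_samples = n_samples,
              n_subpops = n_subpops,
              theta = theta, divergence = divergence,
              admix_alpha = admix_alpha, selfing = selfing,
              missing_rate = missing_rate, mean_depth = mean_depth,
              depth_bin = depth_bin, indel_fraction = indel_fraction,
              linkage = linkage,
              sweeps = sweeps, balancing = balancing,
              cnv_events = cnv_events, pav_events = pav_events,
              seed = as.integer(seed))
  class(cfg) <- "panel_config"
  cfg
}

#' Demo configuration with planted events
#'
#' The default demonstration conditions: a 2 x 200 kb genome, a 24-sample
#' panel from 3 admixed subpopulations, one planted sweep, one balancing
#' region, two CNV amplifications and two PAV dropouts.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [panel_config()].
#' @return a \code{panel_config}.
#' @export
demo_config <- function(seed = 1, ...) {
  args <- list(
    linkage = list(n_founders = 12, recomb_rate = 2e-5),
    sweeps = data.frame(chrom = "Ca1", start = 50000, end = 100000,
                        factor = 0.1, subpop = NA),
    balancing = data.frame(chrom = "Ca2", start = 120000, end = 160000,
                           strength = 0.8),
    cnv_events = data.frame(sample = c("v01", "v02"),
                            chrom = c("Ca1", "Ca2"),
                            start = c(120000, 20000),
                            end = c(150000, 50000),
                            copy = c(3, 2)),
    pav_events = data.frame(sample = c("v03", "v04"),
                            chrom = c("Ca2", "Ca1"),
                            start = c(80000, 160000),
                            end = c(95000, 175000),
                            state = "absent", class = "deletion"),
    seed = seed)
  do.call(panel_config, utils::modifyList(args, list(...)))
}

#' Simulate a toy genome with gene models
#'
#' Generates random chromosome sequences and non-overlapping gene models
#' whose CDS intervals cover approximately \code{cds_fraction} of the genome.
#' Each gene has 1--4 CDS exons; total CDS length per gene is divisible by 3.
#'
#' @param config a [panel_config()].
#' @return an object of class \code{genome_model} with elements
#'   \code{chromosomes} (name, length), \code{seq} (a
#'   \code{Biostrings::DNAStringSet}), \code{genes} and \code{cds} data
#'   frames (0-based half-open coordinates).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  chroms <- data.frame(name = names(config$chrom_lengths),
                       length = as.integer(config$chrom_lengths),
                       stringsAsFactors = FALSE)
  seqs <- vapply(chroms$length, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- chroms$name

  genes <- list(); cds <- list(); gid <- 0L
  for (ci in seq_len(nrow(chroms))) {
    L <- chroms$length[ci]
    target <- config$cds_fraction * L
    cds_total <- 0
    structs <- list()
    # draw gene structures until the CDS target is met
    while (cds_total < target) {
      n_ex <- sample(1:4, 1)
      ex_len <- 3 * pmax(50, round(stats::rlnorm(n_ex, log(300), 0.4) / 3))
      introns <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE)
                 else integer(0)
      structs[[length(structs) + 1]] <-
        list(ex = ex_len, intr = introns, span = sum(ex_len) + sum(introns))
      cds_total <- cds_total + sum(ex_len)
    }
    spans <- vapply(structs, `[[`, numeric(1), "span")
    slack <- L - sum(spans)
    if (slack < length(structs) + 1) {  # genome too dense: drop genes
      keep <- cumsum(spans + 1) < L - 1
      structs <- structs[keep]
      spans <- spans[keep]
      slack <- L - sum(spans)
    }
    # random intergenic gaps summing to the slack
    gaps <- if (length(structs) > 0) {
      u <- sort(stats::runif(length(structs)))
      diff(c(0, u, 1)) * slack
    } else numeric(0)
    cursor <- 0
    for (k in seq_along(structs)) {
      cursor <- cursor + floor(gaps[k])
      gid <- gid + 1L
      id <- sprintf("gene%04d", gid)
      strand <- sample(c("+", "-"), 1)
      st <- structs[[k]]
      ex_start <- cursor + cumsum(c(0, utils::head(st$ex, -1) + st$intr))
      ex_end <- ex_start + st$ex
      genes[[gid]] <- data.frame(gene_id = id, chrom = chroms$name[ci],
                                 start = cursor, end = cursor + st$span,
                                 strand = strand, stringsAsFactors = FALSE)
      cds[[gid]] <- data.frame(gene_id = id, chrom = chroms$name[ci],
                               start = ex_start, end = ex_end,
                               strand = strand, stringsAsFactors = FALSE)
      cursor <- cursor + st$span
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  cds <- if (length(cds)) do.call(rbind, cds) else genes
  rownames(genes) <- rownames(cds) <- NULL
  out <- list(chromosomes = chroms,
              seq = Biostrings::DNAStringSet(seqs),
              genes = genes, cds = cds)
  class(out) <- "genome_model"
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.0f bp, %d gene(s)\n",
              nrow(x$chromosomes), sum(x$chromosomes$length), nrow(x$genes)))
  invisible(x)
}

# sample sheet for the standard 6-cell panel layout; n_total trims or
# recycles the cells when an exact panel size is requested
make_sample_sheet <- function(n_per_group, n_total = NULL) {
  grid <- expand.grid(release_period = c("RP1", "RP2", "RP3"),
                      market_type = c("desi", "kabuli"),
                      stringsAsFactors = FALSE)
  if (!is.null(n_total))
    n_per_group <- ceiling(n_total / nrow(grid))
  df <- grid[rep(seq_len(nrow(grid)), each = n_per_group), ]
  if (!is.null(n_total)) df <- df[seq_len(n_total), , drop = FALSE]
  df$sample <- sprintf("v%02d", seq_len(nrow(df)))
  countries <- c("India", "Canada", "Australia", "Ethiopia", "Myanmar")
  df$country <- rep_len(countries, nrow(df))
  rownames(df) <- NULL
  df[, c("sample", "market_type", "release_period", "country")]
}

# scale a frequency's minor side by `factor` (sweep) on counts of nh
scale_minor_count <- function(i, nh, factor) {
  minor <- pmin(i, nh - i)
  minor2 <- pmax(1L, as.integer(round(minor * factor)))
  ifelse(i <= nh - i, minor2, nh - minor2)
}

# Founder-mosaic haplotypes for one chromosome: each subpopulation carries
# n_founders founder haplotypes drawn site-wise from its allele
# frequencies; a sampled haplotype copies one founder and switches to a
# random founder with probability 1 - exp(-rate x gap) between adjacent
# sites (hotspot intervals add extra switch intensity).  Selfing is
# realized as autozygosity: with probability `selfing` the second
# haplotype is a copy of the first.
mosaic_genotypes <- function(pos, Fc, Q0, config, chrom = NULL) {
  S <- length(pos); n <- nrow(Q0); K <- ncol(Fc)
  lk <- config$linkage
  nf <- lk$n_founders
  founders <- lapply(seq_len(K), function(k)
    matrix(stats::rbinom(S * nf, 1L, Fc[, k]), S, nf))
  gap_int <- if (S > 1) {
    gi <- diff(pos) * lk$recomb_rate
    if (!is.null(lk$hotspots)) {
      hs <- lk$hotspots
      if (!is.null(chrom) && !is.null(hs$chrom))
        hs <- hs[hs$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(hs)))
        gi <- gi + hs$rate[r] *
          interval_overlap(pos[-S], pos[-1], hs$start[r], hs$end[r])
    }
    gi
  } else numeric(0)
  p_switch <- 1 - exp(-gap_int)
  draw_hap <- function(i) {
    k <- sample.int(K, 1, prob = Q0[i, ])
    seg <- cumsum(c(TRUE, stats::runif(S - 1) < p_switch))
    f <- sample.int(nf, max(seg), replace = TRUE)[seg]
    founders[[k]][cbind(seq_len(S), f)]
  }
  g <- matrix(0L, S, n)
  for (i in seq_len(n)) {
    h1 <- draw_hap(i)
    h2 <- if (stats::runif(1) < config$selfing) h1 else draw_hap(i)
    g[, i] <- h1 + h2
  }
  g
}

in_region <- function(chrom, pos, reg) {
  hit <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(reg)))
    hit <- hit | (chrom == reg$chrom[r] & pos >= reg$start[r] &
                  pos < reg$end[r])
  hit
}

#' Simulate a structured, mostly-selfing variety panel
#'
#' Draws variant sites from a neutral frequency spectrum at rate
#' \code{theta}, assigns subpopulation frequencies under a Balding--Nichols
#' model, admixes per-sample ancestry from a Dirichlet, collapses
#' heterozygotes at the selfing rate, plants sweeps / balancing regions /
#' CNVs / PAV dropouts, and simulates Poisson depth tracks.  With a single
#' subpopulation, derived alleles are placed on haplotypes by exact
#' assignment, so the realized spectrum is the neutral spectrum itself (the
#' substrate for the neutrality-statistic calibrations).
#'
#' @param genome a [simulate_genome()] result.
#' @param config the same [panel_config()].
#' @return a list with components \code{panel} (class
#'   \code{panel_genotypes}), \code{depth} (class \code{depth_track}) and
#'   \code{truth} (class \code{truth_set}).
#' @export
simulate_panel <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "panel_config"))
  set.seed(config$seed + 1L)
  samples <- make_sample_sheet(config$samples_per_group, config$n_samples)
  n <- nrow(samples)
  nh <- 2L * n
  K <- config$n_subpops
  a1 <- harmonic_a1(nh)

  sweeps <- config$sweeps
  balancing <- config$balancing

  all_sites <- list(); all_geno <- list(); F0 <- list()
  # ancestry proportions
  Q0 <- matrix(stats::rgamma(n * K, shape = config$admix_alpha), n, K)
  # tiny Dirichlet concentrations can underflow a whole row to zero:
  # such samples are effectively unadmixed, assign a random pure ancestry
  zero <- rowSums(Q0) == 0
  if (any(zero))
    Q0[cbind(which(zero), sample.int(K, sum(zero), replace = TRUE))] <- 1
  Q0 <- Q0 / rowSums(Q0)
  rownames(Q0) <- samples$sample

  for (ci in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$name[ci]
    L <- genome$chromosomes$length[ci]
    S <- stats::rpois(1, config$theta * L * a1)
    S <- min(S, L)
    pos <- sort(sample.int(L, S)) - 1L
    i0 <- sample.int(nh - 1L, S, replace = TRUE,
                     prob = 1 / seq_len(nh - 1L))

    # planted sweeps: thin site density and shrink minor frequencies
    if (!is.null(sweeps)) {
      pan <- sweeps[is.na(sweeps$subpop) & sweeps$chrom == chrom, ,
                    drop = FALSE]
      for (r in seq_len(nrow(pan))) {
        hit <- pos >= pan$start[r] & pos < pan$end[r]
        keep <- !hit | stats::runif(S) < pan$factor[r]
        pos <- pos[keep]; i0 <- i0[keep]; S <- length(pos)
        hit <- pos >= pan$start[r] & pos < pan$end[r]
        i0[hit] <- scale_minor_count(i0[hit], nh, pan$factor[r])
      }
    }
    if (!is.null(balancing)) {
      bal <- balancing[balancing$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(bal))) {
        hit <- pos >= bal$start[r] & pos < bal$end[r]
        i0[hit] <- pmin(nh - 1L, pmax(1L, as.integer(
          round(i0[hit] + (nh / 2 - i0[hit]) * bal$strength[r]))))
      }
    }

    # subpopulation allele frequencies (Balding-Nichols around the
    # ancestral frequency), plus subpop-specific planted sweeps
    if (K == 1) {
      Fc <- matrix(i0 / nh, S, 1)
    } else {
      p0 <- i0 / nh
      F <- max(config$divergence, 1e-6)
      Fc <- matrix(suppressWarnings(
        stats::rbeta(S * K,
                     rep(p0, K) * (1 - F) / F,
                     rep(1 - p0, K) * (1 - F) / F)), S, K)
      # rbeta underflows to NaN for tiny shape parameters: fall back to
      # the ancestral frequency there
      bad <- !is.finite(Fc)
      if (any(bad)) Fc[bad] <- matrix(p0, S, K)[bad]
    }
    if (!is.null(sweeps) && K > 1) {
      sub <- sweeps[!is.na(sweeps$subpop) & sweeps$chrom == chrom, ,
                    drop = FALSE]
      for (r in seq_len(nrow(sub))) {
        hit <- pos >= sub$start[r] & pos < sub$end[r]
        k <- sub$subpop[r]
        p <- Fc[hit, k]
        Fc[hit, k] <- ifelse(p <= 0.5, p * sub$factor[r],
                             1 - (1 - p) * sub$factor[r])
      }
    }

    if (!is.null(config$linkage)) {
      g <- mosaic_genotypes(pos, Fc, Q0, config, chrom)
    } else if (K == 1) {
      # exact placement of i derived alleles on the 2n haplotypes
      g <- matrix(0L, S, n)
      for (s in seq_len(S)) {
        hap <- sample.int(nh, i0[s])
        g[s, ] <- tabulate(((hap - 1L) %/% 2L) + 1L, nbins = n)
      }
    } else {
      pind <- Q0 %*% t(Fc)           # n x S individual allele frequencies
      pind <- pmin(pmax(pind, 0), 1) # guard rounding at the boundaries
      g <- matrix(stats::rbinom(n * S, 2L, t(pind)), S, n)
    }

    if (is.null(config$linkage)) {
      # selfing: collapse heterozygotes to a random homozygote (the mosaic
      # model realizes selfing directly as autozygous haplotype pairs)
      het <- which(g == 1L)
      collapse <- het[stats::runif(length(het)) < config$selfing]
      g[collapse] <- 2L * stats::rbinom(length(collapse), 1L, 0.5)
    }

    all_sites[[ci]] <- data.frame(chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE)
    all_geno[[ci]] <- g
    colnames(Fc) <- paste0("subpop", seq_len(K))
    F0[[ci]] <- Fc
  }

  sites <- do.call(rbind, all_sites)
  geno <- do.call(rbind, all_geno)
  F0 <- do.call(rbind, F0)
  nS <- nrow(sites)

  # variant class and alleles from the reference sequence
  cls <- rep("SNP", nS)
  idx <- stats::runif(nS) < config$indel_fraction
  cls[idx] <- sample(c("insertion", "deletion"), sum(idx), replace = TRUE)
  ilen <- integer(nS)
  ilen[idx] <- sample.int(10L, sum(idx), replace = TRUE,
                          prob = 0.55^(1:10))
  bases <- c("A", "C", "G", "T")
  ref <- alt <- character(nS)
  for (ci in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$name[ci]
    sel <- which(sites$chrom == chrom)
    if (!length(sel)) next
    sq <- as.character(genome$seq[[chrom]])
    refbase <- substring(sq, sites$pos[sel] + 1, sites$pos[sel] + 1)
    ref[sel] <- refbase
    alt[sel] <- vapply(refbase, function(b) sample(setdiff(bases, b), 1),
                       character(1))
    for (s in sel[cls[sel] == "insertion"]) {
      ins <- paste(sample(bases, ilen[s], replace = TRUE), collapse = "")
      alt[s] <- paste0(ref[s], ins)
    }
    for (s in sel[cls[sel] == "deletion"]) {
      Lc <- genome$chromosomes$length[ci]
      end <- min(sites$pos[s] + 1 + ilen[s], Lc)
      ref[s] <- substring(sq, sites$pos[s] + 1, end)
      alt[s] <- substring(ref[s], 1, 1)
    }
  }
  sites$ref <- ref; sites$alt <- alt; sites$class <- cls

  # missingness
  miss <- matrix(stats::runif(nS * n) < config$missing_rate, nS, n)
  geno[miss] <- NA_integer_

  # depth track with planted CNV/PAV multipliers
  cnv <- config$cnv_events
  pav <- config$pav_events
  if (!is.null(cnv) || !is.null(pav)) {
    ev <- rbind(
      if (!is.null(cnv)) cnv[, c("sample", "chrom", "start", "end")],
      if (!is.null(pav)) pav[, c("sample", "chrom", "start", "end")])
    for (sm in unique(ev$sample)) {
      e <- ev[ev$sample == sm, , drop = FALSE]
      e <- e[order(e$chrom, e$start), ]
      if (nrow(e) > 1) {
        same <- e$chrom[-1] == e$chrom[-nrow(e)]
        if (any(same & e$start[-1] < e$end[-nrow(e)]))
          stop_config("overlapping planted structural events in sample %s", sm)
      }
    }
  }

  bins <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
    L <- genome$chromosomes$length[ci]
    st <- seq(0L, L - 1L, by = config$depth_bin)
    data.frame(chrom = genome$chromosomes$name[ci], start = st,
               end = pmin(st + config$depth_bin, L),
               stringsAsFactors = FALSE)
  }))
  nb <- nrow(bins)
  mult <- matrix(1, nb, n, dimnames = list(NULL, samples$sample))
  if (!is.null(pav)) {
    ins_reg <- unique(pav[pav$class == "insertion",
                          c("chrom", "start", "end"), drop = FALSE])
    for (r in seq_len(nrow(ins_reg))) {
      hit <- bins$chrom == ins_reg$chrom[r] & bins$start < ins_reg$end[r] &
        bins$end > ins_reg$start[r]
      mult[hit, ] <- 0.05   # novel segment: absent unless planted present
    }
    for (r in seq_len(nrow(pav))) {
      hit <- bins$chrom == pav$chrom[r] & bins$start < pav$end[r] &
        bins$end > pav$start[r]
      mult[hit, pav$sample[r]] <-
        if (pav$state[r] == "absent") 0.05 else 1
    }
  }
  if (!is.null(cnv)) {
    for (r in seq_len(nrow(cnv))) {
      hit <- bins$chrom == cnv$chrom[r] & bins$start < cnv$end[r] &
        bins$end > cnv$start[r]
      mult[hit, cnv$sample[r]] <- cnv$copy[r]
    }
  }
  depth_mat <- matrix(stats::rpois(nb * n, config$mean_depth * mult), nb, n,
                      dimnames = list(NULL, samples$sample))
  track <- structure(list(bins = bins, depth = depth_mat,
                          samples = samples$sample,
                          mean_depth = colMeans(depth_mat),
                          bin_width = config$depth_bin),
                     class = "depth_track")

  # per-site, per-sample depth follows the bin multiplier
  site_mult <- matrix(1, nS, n)
  bin_of_site <- match(
    paste(sites$chrom, (sites$pos %/% config$depth_bin) * config$depth_bin),
    paste(bins$chrom, bins$start))
  site_mult <- mult[bin_of_site, , drop = FALSE]
  site_depth <- matrix(stats::rpois(nS * n, config$mean_depth * site_mult),
                       nS, n, dimnames = list(NULL, samples$sample))

  panel <- structure(list(sites = sites, geno = geno, depth = site_depth,
                          samples = samples),
                     class = "panel_genotypes")
  truth <- structure(list(sites = cbind(sites[, c("chrom", "pos", "class")],
                                        F0),
                          sweeps = sweeps, balancing = balancing,
                          cnv_events = cnv, pav_events = pav,
                          Q0 = Q0),
                     class = "truth_set")
  list(panel = panel, depth = track, truth = truth)
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat(sprintf("panel_genotypes: %d sites x %d samples (%d SNP, %d indel)\n",
              nrow(x$sites), nrow(x$samples), sum(x$sites$class == "SNP"),
              sum(x$sites$class != "SNP")))
  invisible(x)
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d bins (%d bp) x %d samples, mean depth %.1f\n",
              nrow(x$bins), x$bin_width, length(x$samples),
              mean(x$mean_depth)))
  invisible(x)
}

#' Subset a panel to selected samples
#' @param panel a \code{panel_genotypes}.
#' @param samples character vector of sample ids.
#' @return a \code{panel_genotypes} restricted to those samples.
#' @export
subset_samples <- function(panel, samples) {
  keep <- panel$samples$sample %in% samples
  if (!any(keep)) stop_config("no matching samples")
  panel$geno <- panel$geno[, keep, drop = FALSE]
  panel$depth <- panel$depth[, keep, drop = FALSE]
  panel$samples <- panel$samples[keep, , drop = FALSE]
  panel
}
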