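# Variant filtering cascade and annotation: pooled-depth / copy-number /
# missingness / fixed-frequency filters, genic-context and coding-effect
# classification, Nei-Gojobori dN/dS and the release-period Venn partition.

#' Variant filter policy
#'
#' The filtering cascade retains sites with pooled depth inside a stated
#' range, mean relative copy number at most \code{cn_max}, missing ratio at
#' most \code{max_missing}, and panel alt-allele frequency not 0 or 1.
#' The depth range [78, 2500] was calibrated on a 129-sample panel at
#' ~10x mean depth; for panels of a different size the default scales to
#' 0.6x--20x of (n_samples x mean_depth), while a 129-sample panel keeps
#' the literal bounds.
#'
#' @param n_samples panel size (used to scale the default depth range).
#' @param mean_depth mean per-sample depth (used with \code{n_samples}).
#' @param depth_range explicit pooled-depth range, overriding the default.
#' @param cn_max relative copy-number ceiling (default 1.5).
#' @param max_missing maximum per-site missing genotype ratio (default 0.5).
#' @return an object of class \code{filter_policy}.
#' @export
filter_policy <- function(n_samples = 129, mean_depth = 10,
                          depth_range = NULL, cn_max = 1.5,
                          max_missing = 0.5) {
  if (is.null(depth_range)) {
    depth_range <- if (n_samples == 129) c(78, 2500) else
      c(0.6, 20) * n_samples * mean_depth
  }
  if (length(depth_range) != 2 || depth_range[1] >= depth_range[2])
    stop_config("depth_range must be an increasing pair")
  if (cn_max <= 0 || max_missing < 0 || max_missing > 1)
    stop_config("invalid filter ceilings")
  structure(list(depth_range = depth_range, cn_max = cn_max,
                 max_missing = max_missing, exclude_fixed = TRUE),
            class = "filter_policy")
}

subset_sites <- function(panel, idx) {
  panel$sites <- panel$sites[idx, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel$geno <- panel$geno[idx, , drop = FALSE]
  panel$depth <- panel$depth[idx, , drop = FALSE]
  panel
}

#' Apply the variant filtering cascade
#'
#' @param panel a \code{panel_genotypes}.
#' @param policy a [filter_policy()].
#' @param cn_track optional \code{depth_track} supplying each sample's
#'   genome-wide mean depth for copy-number normalization; defaults to the
#'   panel's own per-sample mean site depth.
#' @return a list with \code{panel} (retained sites, order preserved) and
#'   \code{ledger}, a per-site data frame with the retained flag and a
#'   comma-joined reason string ("depth", "copy_number", "missing",
#'   "fixed") for removed sites.
#' @export
filter_variants <- function(panel, policy = filter_policy(
                              nrow(panel$samples),
                              mean(panel$depth, na.rm = TRUE)),
                            cn_track = NULL) {
  if (nrow(panel$sites) == 0) stop_config("empty panel")
  pooled <- rowSums(panel$depth, na.rm = TRUE)
  means <- if (!is.null(cn_track))
    cn_track$mean_depth[match(panel$samples$sample, cn_track$samples)]
  else colMeans(panel$depth, na.rm = TRUE)
  rel_cn <- rowMeans(sweep(panel$depth, 2, means, "/"), na.rm = TRUE)
  miss <- rowMeans(is.na(panel$geno))
  m <- 2 * rowSums(!is.na(panel$geno))
  x <- rowSums(panel$geno, na.rm = TRUE)
  freq <- ifelse(m > 0, x / m, NA_real_)

  bad_depth <- pooled < policy$depth_range[1] | pooled > policy$depth_range[2]
  bad_cn <- rel_cn > policy$cn_max
  bad_miss <- miss > policy$max_missing
  bad_fixed <- is.na(freq) | freq == 0 | freq == 1
  keep <- !(bad_depth | bad_cn | bad_miss | bad_fixed)

  reason <- character(nrow(panel$sites))
  add <- function(reason, bad, tag)
    ifelse(bad, ifelse(reason == "", tag, paste(reason, tag, sep = ",")),
           reason)
  reason <- add(reason, bad_depth, "depth")
  reason <- add(reason, bad_cn, "copy_number")
  reason <- add(reason, bad_miss, "missing")
  reason <- add(reason, bad_fixed, "fixed")
  ledger <- data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                       retained = keep, reason = reason,
                       stringsAsFactors = FALSE)
  list(panel = subset_sites(panel, keep), ledger = ledger)
}

#' Classify genic context of positions
#'
#' A position is exonic if it lies in any CDS interval, intronic if it lies
#' within a gene span but in no CDS, and intergenic otherwise.
#'
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @param genome a \code{genome_model}.
#' @return factor with levels exonic, intronic, intergenic.
#' @export
classify_genic_context <- function(chrom, pos, genome) {
  lens <- stats::setNames(genome$chromosomes$length,
                          genome$chromosomes$name)
  if (any(!chrom %in% names(lens)) || any(pos < 0) ||
      any(pos >= lens[chrom]))
    stop_config("position outside chromosome bounds")
  in_cds <- if (nrow(genome$cds)) in_region(chrom, pos, genome$cds)
            else rep(FALSE, length(pos))
  in_gene <- if (nrow(genome$genes)) in_region(chrom, pos, genome$genes)
             else rep(FALSE, length(pos))
  factor(ifelse(in_cds, "exonic", ifelse(in_gene, "intronic", "intergenic")),
         levels = c("exonic", "intronic", "intergenic"))
}

# genomic positions of a gene's CDS in transcription order (0-based)
cds_positions <- function(cds_rows) {
  d <- cds_rows[order(cds_rows$start), , drop = FALSE]
  p <- unlist(mapply(seq, d$start, d$end - 1L, SIMPLIFY = FALSE))
  if (d$strand[1] == "-") rev(p) else p
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Classify the coding effect of SNPs
#'
#' Translates the reference and alternate codon with the standard nuclear
#' codon table: same amino acid is silent, a gained stop is nonsense,
#' anything else missense.  Reverse-strand genes use the reverse
#' complement.  Indels and non-exonic sites return "not-applicable".
#'
#' @param panel a \code{panel_genotypes}.
#' @param genome a \code{genome_model}.
#' @param context optional precomputed genic-context factor.
#' @return character vector: missense, nonsense, silent or not-applicable.
#' @export
classify_coding_effect <- function(panel, genome, context = NULL) {
  s <- panel$sites
  if (is.null(context))
    context <- classify_genic_context(s$chrom, s$pos, genome)
  eff <- rep("not-applicable", nrow(s))
  cand <- which(context == "exonic" & s$class == "SNP")
  if (!length(cand)) return(eff)
  code <- Biostrings::GENETIC_CODE
  for (i in cand) {
    hit <- genome$cds$chrom == s$chrom[i] & genome$cds$start <= s$pos[i] &
      genome$cds$end > s$pos[i]
    gid <- genome$cds$gene_id[hit][1]
    rows <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
    tx <- cds_positions(rows)
    off <- match(s$pos[i], tx) - 1L
    cstart <- (off %/% 3L) * 3L
    cod_pos <- tx[cstart + 1:3]
    sq <- as.character(genome$seq[[s$chrom[i]]])
    b <- substring(sq, cod_pos + 1L, cod_pos + 1L)
    ref_b <- s$ref[i]; alt_b <- s$alt[i]
    if (rows$strand[1] == "-") {
      b <- complement_base(b)
      ref_b <- complement_base(ref_b); alt_b <- complement_base(alt_b)
    }
    within <- off %% 3L + 1L
    ref_cod <- b; ref_cod[within] <- ref_b
    alt_cod <- b; alt_cod[within] <- alt_b
    aa_ref <- code[paste(ref_cod, collapse = "")]
    aa_alt <- code[paste(alt_cod, collapse = "")]
    eff[i] <- if (aa_alt == aa_ref) "silent"
      else if (aa_alt == "*" && aa_ref != "*") "nonsense"
      else "missense"
  }
  eff
}

#' Annotate a panel with genic context and coding effect
#'
#' @inheritParams classify_coding_effect
#' @return data frame (chrom, pos, class, context, effect, synonymous);
#'   \code{synonymous} is TRUE for silent exonic SNPs, FALSE for
#'   missense/nonsense, NA otherwise.
#' @export
annotate_variants <- function(panel, genome) {
  ctx <- classify_genic_context(panel$sites$chrom, panel$sites$pos, genome)
  eff <- classify_coding_effect(panel, genome, context = ctx)
  data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
             class = panel$sites$class, context = ctx, effect = eff,
             synonymous = ifelse(eff == "not-applicable", NA,
                                 eff == "silent"),
             stringsAsFactors = FALSE)
}

# Nei-Gojobori (1986) synonymous/non-synonymous site fractions per codon:
# a 64 x 3 matrix of the synonymous fraction of the 3 possible changes at
# each codon position (changes to/from stop counted as non-synonymous
# unless the amino acid is preserved).
codon_site_table <- function() {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, length(code), 3, dimnames = list(names(code), NULL))
  for (cod in names(code)) {
    sp <- strsplit(cod, "")[[1]]
    for (j in 1:3) {
      syn <- 0
      for (b in setdiff(bases, sp[j])) {
        mut <- sp; mut[j] <- b
        if (code[paste(mut, collapse = "")] == code[cod]) syn <- syn + 1
      }
      m[cod, j] <- syn / 3
    }
  }
  m
}

#' Nei-Gojobori synonymous and non-synonymous site counts for a gene set
#'
#' @param genome a \code{genome_model}.
#' @return list with \code{syn_sites} and \code{nonsyn_sites}.
#' @export
ng86_site_counts <- function(genome) {
  tab <- codon_site_table()
  syn <- 0; nonsyn <- 0
  for (gid in unique(genome$cds$gene_id)) {
    rows <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
    tx <- cds_positions(rows)
    sq <- as.character(genome$seq[[rows$chrom[1]]])
    b <- substring(sq, tx + 1L, tx + 1L)
    if (rows$strand[1] == "-") b <- complement_base(b)
    cods <- paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
                   b[c(FALSE, FALSE, TRUE)])
    fr <- tab[cods, , drop = FALSE]
    syn <- syn + sum(fr)
    nonsyn <- nonsyn + sum(1 - fr)
  }
  list(syn_sites = syn, nonsyn_sites = nonsyn)
}

# resolve a grouping argument into a factor over samples
resolve_grouping <- function(panel, grouping) {
  if (is.null(grouping)) return(factor(rep("all", nrow(panel$samples))))
  if (is.character(grouping) && length(grouping) == 1) {
    if (!grouping %in% names(panel$samples))
      stop_config("unknown grouping column '%s'", grouping)
    g <- panel$samples[[grouping]]
  } else g <- grouping
  if (length(g) != nrow(panel$samples) || any(is.na(g)))
    stop_config("every sample needs a group label")
  factor(g)
}

#' dN/dS summary per group
#'
#' Counts non-synonymous and synonymous exonic SNPs segregating within each
#' group and divides per-substitution rates by the Nei-Gojobori site
#' counts of the gene set: (nonsyn / N sites) / (syn / S sites).  Groups
#' with zero synonymous substitutions report NA rather than infinity.
#'
#' @param panel a \code{panel_genotypes}.
#' @param genome a \code{genome_model}.
#' @param grouping a sample-sheet column name, a per-sample vector, or NULL
#'   for a single panel-wide row.
#' @param annotations optional precomputed [annotate_variants()] table.
#' @return data frame with group, substitution counts, site counts and dnds.
#' @export
dnds_summary <- function(panel, genome, grouping = NULL,
                         annotations = NULL) {
  if (is.null(annotations)) annotations <- annotate_variants(panel, genome)
  grp <- resolve_grouping(panel, grouping)
  sites <- ng86_site_counts(genome)
  ex <- annotations$effect != "not-applicable"
  out <- lapply(levels(grp), function(g) {
    gi <- grp == g
    x <- rowSums(panel$geno[, gi, drop = FALSE], na.rm = TRUE) > 0
    nonsyn <- sum(ex & x & annotations$effect %in% c("missense", "nonsense"))
    syn <- sum(ex & x & annotations$effect == "silent")
    dnds <- if (syn == 0) NA_real_ else
      (nonsyn / sites$nonsyn_sites) / (syn / sites$syn_sites)
    data.frame(group = g, nonsyn = nonsyn, syn = syn,
               nonsyn_sites = sites$nonsyn_sites,
               syn_sites = sites$syn_sites, dnds = dnds,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Venn partition of sites across groups
#'
#' Assigns each site to the subset of groups in which the alternate allele
#' is observed (count >= 1 among non-missing calls), and returns the
#' 2^k - 1 cell counts, which sum to the total site count.
#'
#' @inheritParams dnds_summary
#' @return named integer vector over group subsets (names joined with "&").
#' @export
partition_by_groups <- function(panel, grouping) {
  grp <- resolve_grouping(panel, grouping)
  ks <- levels(grp)
  present <- vapply(ks, function(g)
    rowSums(panel$geno[, grp == g, drop = FALSE], na.rm = TRUE) > 0,
    logical(nrow(panel$sites)))
  if (nrow(panel$sites) == 1) present <- matrix(present, nrow = 1)
  # all non-empty subsets
  subsets <- unlist(lapply(seq_along(ks), function(r)
    utils::combn(ks, r, paste, collapse = "&", simplify = FALSE)))
  cells <- stats::setNames(integer(length(subsets)), subsets)
  key <- apply(present, 1, function(z) paste(ks[z], collapse = "&"))
  tab <- table(key[key != ""])
  cells[names(tab)] <- as.integer(tab)
  cells
}
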