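# Filtering cascade, genic-context and coding-effect annotation, dN/dS and
# the group Venn partition.

test_that("each filter rule removes exactly the offending sites", {
  set.seed(42)
  n <- 20
  ns <- 100
  geno <- matrix(sample(c(0L, 2L), ns * n, TRUE, prob = c(0.7, 0.3)),
                 ns, n)
  depth <- matrix(rpois(ns * n, 10), ns, n)
  # plant 7 violations, one rule each
  geno[1, ] <- 0L                      # fixed ref
  geno[2, ] <- 2L                      # fixed alt
  geno[3, 1:11] <- NA                  # missing ratio 0.55
  depth[4, ] <- 1L                     # pooled depth below range
  depth[5, ] <- 500L                   # pooled depth above range
  depth[6, ] <- 40L                    # relative copy number 4
  geno[7, 12:20] <- NA                 # missing ratio 0.45 -> retained
  geno[7, 1:11] <- c(rep(0L, 10), 2L)
  panel <- make_panel(geno, depth = depth)
  pol <- filter_policy(n_samples = n, mean_depth = 10)
  res <- filter_variants(panel, pol)

  led <- res$ledger
  expect_false(led$retained[1]); expect_match(led$reason[1], "fixed")
  expect_false(led$retained[2]); expect_match(led$reason[2], "fixed")
  expect_false(led$retained[3]); expect_match(led$reason[3], "missing")
  expect_false(led$retained[4]); expect_match(led$reason[4], "depth")
  expect_false(led$retained[5]); expect_match(led$reason[5], "depth")
  expect_false(led$retained[6]); expect_match(led$reason[6], "copy_number")
  expect_true(led$retained[7])

  # independent per-site re-check of every rule
  means <- colMeans(depth)
  for (i in seq_len(ns)) {
    pooled <- sum(depth[i, ])
    cn <- mean(depth[i, ] / means)
    miss <- mean(is.na(geno[i, ]))
    x <- sum(geno[i, ], na.rm = TRUE)
    m <- 2 * sum(!is.na(geno[i, ]))
    ok <- pooled >= pol$depth_range[1] && pooled <= pol$depth_range[2] &&
      cn <= 1.5 && miss <= 0.5 && m > 0 && x > 0 && x < m
    expect_equal(led$retained[i], ok)
  }
  expect_equal(nrow(res$panel$sites), sum(led$retained))

  # idempotence
  res2 <- filter_variants(res$panel, pol)
  expect_equal(res2$panel$sites, res$panel$sites)
  expect_true(all(res2$ledger$retained))

  # error contracts
  expect_error(filter_variants(subset_sites(panel, integer(0)), pol),
               "empty")
  expect_error(filter_policy(depth_range = c(10, 5)), "increasing")
})

test_that("the 129-sample policy keeps the literal depth bounds", {
  expect_equal(filter_policy(129, 10)$depth_range, c(78, 2500))
  expect_equal(filter_policy(20, 10)$depth_range, c(120, 4000))
})

test_that("genic context matches a naive interval scan on random positions", {
  cfg <- panel_config(chrom_lengths = c(Ca1 = 100000, Ca2 = 100000),
                      seed = 13)
  g <- simulate_genome(cfg)
  set.seed(5)
  chrom <- sample(c("Ca1", "Ca2"), 1000, TRUE)
  pos <- sample.int(100000, 1000, TRUE) - 1L
  ctx <- classify_genic_context(chrom, pos, g)
  for (i in seq_len(1000)) {
    in_cds <- any(g$cds$chrom == chrom[i] & g$cds$start <= pos[i] &
                    g$cds$end > pos[i])
    in_gene <- any(g$genes$chrom == chrom[i] & g$genes$start <= pos[i] &
                     g$genes$end > pos[i])
    expected <- if (in_cds) "exonic" else if (in_gene) "intronic"
                else "intergenic"
    expect_equal(as.character(ctx[i]), expected)
  }
  expect_error(classify_genic_context("Ca1", 100000, g), "bounds")
})

test_that("coding effects match exhaustive codon-table enumeration", {
  # one plus-strand gene: codons GAA TGG TAC (positions 0..8)
  sq <- paste0("GAATGGTAC", paste(rep("T", 91), collapse = ""))
  gen <- make_genome(
    c(Ca1 = sq),
    genes = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L,
                       end = 9L, strand = "+"),
    cds = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L, end = 9L,
                     strand = "+"))
  # GAA -> GAG silent (third position); GAA -> TAA nonsense (first)
  p <- make_panel(matrix(c(0L, 2L), 2, 2), pos = c(2L, 0L),
                  ref = c("A", "G"), alt = c("G", "T"))
  eff <- classify_coding_effect(p, gen)
  expect_equal(eff, c("silent", "nonsense"))

  # all 9 single-base mutations of the TGG codon at positions 3..5
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  ref_cod <- c("T", "G", "G")
  for (j in 1:3) for (b in setdiff(bases, ref_cod[j])) {
    mut <- ref_cod; mut[j] <- b
    expected <- if (code[paste(mut, collapse = "")] == code["TGG"]) "silent"
      else if (code[paste(mut, collapse = "")] == "*") "nonsense"
      else "missense"
    pp <- make_panel(matrix(2L, 1, 2), pos = 2L + j,
                     ref = ref_cod[j], alt = b)
    expect_equal(classify_coding_effect(pp, gen), expected,
                 label = sprintf("TGG pos %d -> %s", j, b))
  }

  # indels in CDS are not-applicable, without error
  pi <- make_panel(matrix(2L, 1, 2), pos = 4L, ref = "G", alt = "GA",
                   class = "insertion")
  expect_equal(classify_coding_effect(pi, gen), "not-applicable")
})

test_that("reverse-strand effects use the reverse complement", {
  # minus-strand gene over positions 0..5; genomic CATCAT reads as
  # ATG ATG on the minus strand (transcription right to left)
  sq <- paste0("CATCAT", paste(rep("G", 94), collapse = ""))
  gen <- make_genome(
    c(Ca1 = sq),
    genes = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L,
                       end = 6L, strand = "-"),
    cds = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L, end = 6L,
                     strand = "-"))
  # genomic A->G at position 4 is T->C at codon position 2 of the first
  # codon (ATG -> ACG): Met -> Thr, missense
  p <- make_panel(matrix(2L, 1, 2), pos = 4L, ref = "A", alt = "G")
  expect_equal(classify_coding_effect(p, gen), "missense")
  # genomic T->C at position 5 is A->G at codon position 1 (ATG -> GTG)
  p2 <- make_panel(matrix(2L, 1, 2), pos = 5L, ref = "T", alt = "C")
  expect_equal(classify_coding_effect(p2, gen), "missense")
})

test_that("effect classes partition exonic SNPs and contexts all sites", {
  cfg <- panel_config(chrom_lengths = c(Ca1 = 100000), seed = 17)
  g <- simulate_genome(cfg)
  sim <- simulate_panel(g, cfg)
  ann <- annotate_variants(sim$panel, g)
  expect_equal(sum(table(ann$context)), nrow(sim$panel$sites))
  exonic_snp <- ann$context == "exonic" & ann$class == "SNP"
  expect_true(all(ann$effect[exonic_snp] %in%
                    c("missense", "nonsense", "silent")))
  expect_true(all(ann$effect[!exonic_snp] == "not-applicable"))
})

test_that("dN/dS matches a per-codon site-counting oracle", {
  # single 2-codon gene TTT GAA; NG86 site counts enumerated by hand:
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- 0
  for (cod in c("TTT", "GAA")) {
    sp <- strsplit(cod, "")[[1]]
    for (j in 1:3) for (b in setdiff(bases, sp[j])) {
      mut <- sp; mut[j] <- b
      if (code[paste(mut, collapse = "")] == code[cod])
        syn_sites <- syn_sites + 1 / 3
    }
  }
  nonsyn_sites <- 6 - syn_sites
  sq <- paste0("TTTGAA", paste(rep("C", 94), collapse = ""))
  gen <- make_genome(
    c(Ca1 = sq),
    genes = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L,
                       end = 6L, strand = "+"),
    cds = data.frame(gene_id = "g1", chrom = "Ca1", start = 0L, end = 6L,
                     strand = "+"))
  sc <- ng86_site_counts(gen)
  expect_equal(sc$syn_sites, syn_sites, tolerance = 1e-9)
  expect_equal(sc$nonsyn_sites, nonsyn_sites, tolerance = 1e-9)

  # 1 nonsyn (TTT->TAT pos 1 of codon 1... position 1: T->A) + 1 syn
  # (GAA->GAG, position 5)
  p <- make_panel(matrix(2L, 2, 4), pos = c(1L, 5L), ref = c("T", "A"),
                  alt = c("A", "G"))
  tab <- dnds_summary(p, gen)
  expect_equal(tab$nonsyn, 1)
  expect_equal(tab$syn, 1)
  expect_equal(tab$dnds, (1 / nonsyn_sites) / (1 / syn_sites),
               tolerance = 1e-9)

  # only silent substitutions -> dN/dS = 0; zero syn -> NA sentinel
  ps <- make_panel(matrix(2L, 1, 4), pos = 5L, ref = "A", alt = "G")
  expect_equal(dnds_summary(ps, gen)$dnds, 0)
  pn <- make_panel(matrix(2L, 1, 4), pos = 1L, ref = "T", alt = "A")
  expect_true(is.na(dnds_summary(pn, gen)$dnds))

  # two identical groups give identical ratios
  p$samples$market_type <- rep(c("desi", "kabuli"), each = 2)
  p$geno[, 3:4] <- p$geno[, 1:2]
  tab2 <- dnds_summary(p, gen, grouping = "market_type")
  expect_equal(tab2$dnds[1], tab2$dnds[2])
})

test_that("group partition equals brute-force set construction", {
  set.seed(8)
  n <- 12
  geno <- matrix(sample(c(0L, 0L, 2L, NA), 30 * n, TRUE), 30, n)
  # keep every site polymorphic somewhere
  geno[rowSums(geno, na.rm = TRUE) == 0, 1] <- 2L
  panel <- make_panel(geno, rp = rep(c("RP1", "RP2", "RP3"), each = 4))
  cells <- partition_by_groups(panel, "release_period")
  expect_equal(sum(cells), 30)
  expect_length(cells, 7)

  brute <- character(30)
  for (i in 1:30) {
    grs <- c()
    for (g in c("RP1", "RP2", "RP3")) {
      cols <- panel$samples$release_period == g
      if (sum(geno[i, cols], na.rm = TRUE) > 0) grs <- c(grs, g)
    }
    brute[i] <- paste(grs, collapse = "&")
  }
  for (cell in names(cells))
    expect_equal(unname(cells[cell]), sum(brute == cell), label = cell)

  # single-group alt allele lands in the singleton cell
  g1 <- matrix(0L, 1, n); g1[1, 9] <- 2L   # sample 9 is RP3
  p1 <- make_panel(g1, rp = rep(c("RP1", "RP2", "RP3"), each = 4))
  c1 <- partition_by_groups(p1, "release_period")
  expect_equal(unname(c1["RP3"]), 1L)
  expect_equal(sum(c1), 1L)

  # label error
  p2 <- panel
  p2$samples$release_period[1] <- NA
  expect_error(partition_by_groups(p2, "release_period"), "label")
})
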