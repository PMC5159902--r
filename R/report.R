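# Summary tables (cohort x variant-category counts with enforced
# additivity) and the end-to-end pipeline driver.

#' Reference variant-count table for a 129-variety chickpea panel
#'
#' Genome-wide SNP/indel/CNV/PAV counts, split by genic context, for a
#' re-sequenced panel of 129 chickpea varieties (88 desi, 41 kabuli;
#' release-period cohorts RP1/RP2/RP3), shipped as a plain-text fixture.
#' Used to exercise the additivity contract of [build_summary_from_counts()]
#' on realistic magnitudes.
#'
#' @return data frame of cohort rows and count columns.
#' @export
chickpea_variant_counts <- function() {
  utils::read.table(system.file("extdata", "chickpea_variant_counts.tsv",
                                package = "chickdiv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reference insertion/deletion partition for the same panel
#' @return data frame with class (insertion, deletion, total) and count.
#' @export
chickpea_indel_partition <- function() {
  utils::read.table(system.file("extdata", "chickpea_indel_partition.tsv",
                                package = "chickdiv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Recompute category totals from a count table
#'
#' Sums the exon/intron/intergenic category columns into
#' \code{snp_total} / \code{indel_total}, replacing any totals present.
#'
#' @param counts data frame with the category columns of
#'   [chickpea_variant_counts()].
#' @return the table with recomputed totals.
#' @export
build_summary_from_counts <- function(counts) {
  counts$snp_total <- counts$snp_exon + counts$snp_intron +
    counts$snp_intergenic
  counts$indel_total <- counts$indel_exon + counts$indel_intron +
    counts$indel_intergenic
  counts
}

#' Check the additivity invariant of a summary table
#' @param counts a summary table with category and total columns.
#' @return TRUE invisibly; stops if any total mismatches its parts.
#' @export
check_additivity <- function(counts) {
  rec <- build_summary_from_counts(counts)
  if (any(rec$snp_total != counts$snp_total) ||
      any(rec$indel_total != counts$indel_total))
    stop_config("summary table violates additivity")
  invisible(TRUE)
}

#' Cohort summary of variant counts
#'
#' Builds the cohort x category summary (SNPs and indels by genic context
#' plus totals, CNV and PAV counts) for the full panel, each market type
#' and each release period.  A variant belongs to a cohort when its
#' alternate allele is observed among the cohort's non-missing calls; CNV
#' counts are call rows for cohort samples; PAV counts are region-sample
#' entries in the variant state among cohort samples.
#'
#' @param panel a \code{panel_genotypes} (post-filtering).
#' @param annotations [annotate_variants()] table for the same sites.
#' @param cnv_calls [call_cnvs()] data frame (may be empty).
#' @param pav_states [call_pav_matrix()] matrix (may be NULL).
#' @param pav_regions region table matching \code{pav_states}.
#' @return data frame of class \code{summary_table}.
#' @export
build_summary <- function(panel, annotations, cnv_calls = NULL,
                          pav_states = NULL, pav_regions = NULL) {
  if (nrow(annotations) != nrow(panel$sites))
    stop_config("annotations do not match the panel")
  sm <- panel$samples
  cohorts <- c(list(all = sm$sample),
               split(sm$sample, sm$market_type),
               split(sm$sample, sm$release_period))
  rows <- lapply(names(cohorts), function(nm) {
    ids <- cohorts[[nm]]
    cols <- sm$sample %in% ids
    present <- rowSums(panel$geno[, cols, drop = FALSE], na.rm = TRUE) > 0
    cnt <- function(cl, ctx)
      sum(present & (panel$sites$class %in% cl) &
            annotations$context == ctx)
    ncnv <- if (is.null(cnv_calls) || !nrow(cnv_calls)) 0L
            else sum(cnv_calls$sample %in% ids)
    npav <- if (is.null(pav_states)) 0L else {
      vs <- ifelse(pav_regions$class == "deletion", "absent", "present")
      sum(pav_states[, colnames(pav_states) %in% ids, drop = FALSE] == vs)
    }
    ind <- c("insertion", "deletion")
    data.frame(cohort = nm, n_genotypes = length(ids),
               snp_exon = cnt("SNP", "exonic"),
               snp_intron = cnt("SNP", "intronic"),
               snp_intergenic = cnt("SNP", "intergenic"),
               indel_exon = cnt(ind, "exonic"),
               indel_intron = cnt(ind, "intronic"),
               indel_intergenic = cnt(ind, "intergenic"),
               cnv = ncnv, pav = npav, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- build_summary_from_counts(out)
  out <- out[, c("cohort", "n_genotypes", "snp_exon", "snp_intron",
                 "snp_intergenic", "snp_total", "indel_exon",
                 "indel_intron", "indel_intergenic", "indel_total",
                 "cnv", "pav")]
  class(out) <- c("summary_table", "data.frame")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic panel
#'
#' Executes simulate, filter, annotate, cnv, pav, stats, scan, structure,
#' ld and report in order, writing each stage's outputs plus a JSON
#' manifest to \code{out_dir}.  A rerun regenerates only the stages whose
#' outputs are missing (and everything downstream of the first such
#' stage); outputs are byte-identical across reruns of the same
#' configuration.
#'
#' @param config a [panel_config()] (default [demo_config()]).
#' @param out_dir output directory.
#' @param window_size diversity window size in bp.
#' @param scan_min_span minimum selection-region span in bp (demo scale).
#' @param ld_max_dist maximum LD pair distance in bp.
#' @param admixture_k number of admixture clusters (default: the
#'   configuration's subpopulation count).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = demo_config(), out_dir,
                         window_size = 10000, scan_min_span = 30000,
                         ld_max_dist = 100000,
                         admixture_k = config$n_subpops) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_files <- list(
    simulate = c("genome.gff3", "panel.vcf.gz", "samples.tsv",
                 "truth.json"),
    filter = c("filtered_sites.tsv", "filter_ledger.tsv"),
    annotate = "annotations.tsv",
    cnv = "cnv_calls.tsv",
    pav = c("pav_states.tsv", "gene_loss_spectrum.tsv"),
    stats = "window_stats.tsv",
    scan = "selection_regions.tsv",
    structure = c("nj_tree.nwk", "pca_eigenvalues.tsv", "admixture_q.tsv"),
    ld = c("ld_decay.tsv", "haplotype_blocks.tsv"),
    report = c("summary.tsv", "manifest.json"))
  have <- vapply(stage_files, function(f)
    all(file.exists(file.path(out_dir, f))), logical(1))
  first_missing <- if (all(have)) length(stage_files) + 1 else
    which(!have)[1]
  redo <- seq_along(stage_files) >= first_missing
  names(redo) <- names(stage_files)
  emit <- function(stage) redo[[stage]]

  # all stages are recomputed in memory (cheap and fully seeded); only the
  # stages at/after the first missing output rewrite their files
  genome <- simulate_genome(config)
  sim <- simulate_panel(genome, config)
  panel <- sim$panel; track <- sim$depth; truth <- sim$truth
  if (emit("simulate")) {
    write_genome_gff3(genome, file.path(out_dir, "genome.gff3"))
    write_panel_vcf(panel, file.path(out_dir, "panel.vcf.gz"))
    write_depth_bedgraph(track, file.path(out_dir, "depth"))
    write_sample_sheet(panel$samples, file.path(out_dir, "samples.tsv"))
    write_truth_json(truth, file.path(out_dir, "truth.json"))
  }

  flt <- filter_variants(panel, cn_track = track)
  fpanel <- flt$panel
  if (emit("filter")) {
    write_tsv(fpanel$sites, file.path(out_dir, "filtered_sites.tsv"))
    write_tsv(flt$ledger, file.path(out_dir, "filter_ledger.tsv"))
  }

  ann <- annotate_variants(fpanel, genome)
  if (emit("annotate"))
    write_tsv(ann, file.path(out_dir, "annotations.tsv"))

  cnv_calls <- call_cnvs(track)
  if (emit("cnv"))
    write_tsv(cnv_calls, file.path(out_dir, "cnv_calls.tsv"))

  pav_regions <- if (!is.null(truth$pav_events))
    unique(truth$pav_events[, c("chrom", "start", "end", "class")])
  else NULL
  pav_states <- if (!is.null(pav_regions))
    call_pav_matrix(track, pav_regions) else NULL
  loss <- call_gene_loss(track, genome)
  if (emit("pav")) {
    if (!is.null(pav_states))
      write_tsv(cbind(pav_regions, as.data.frame(pav_states)),
                file.path(out_dir, "pav_states.tsv"))
    else write_tsv(data.frame(), file.path(out_dir, "pav_states.tsv"))
    write_tsv(data.frame(absent_in = names(loss$spectrum),
                         genes = as.integer(loss$spectrum)),
              file.path(out_dir, "gene_loss_spectrum.tsv"))
  }

  windows <- make_windows(genome, window_size)
  desi <- panel$samples$sample[panel$samples$market_type == "desi"]
  kabuli <- panel$samples$sample[panel$samples$market_type == "kabuli"]
  stats <- diversity_stats(fpanel, windows, groupA = desi, groupB = kabuli)
  if (emit("stats"))
    write_tsv(stats, file.path(out_dir, "window_stats.tsv"))

  set.seed(config$seed + 7L)
  sweeps <- tajima_region_scan(stats, "negative", min_span = scan_min_span)
  bal <- tajima_region_scan(stats, "positive", min_span = scan_min_span)
  diff <- differentiation_scan(stats, top_fraction = 0.05)
  regions <- rbind(sweeps[, c("chrom", "start", "end", "class")],
                   bal[, c("chrom", "start", "end", "class")],
                   if (nrow(diff)) diff[, c("chrom", "start", "end",
                                            "class")])
  if (emit("scan"))
    write_tsv(regions, file.path(out_dir, "selection_regions.tsv"))

  D <- distance_matrix(fpanel)
  tree <- nj_tree(D)
  pca <- pca_genotypes(fpanel)
  adm <- admixture_em(fpanel, K = admixture_k, max_iter = 500,
                      restarts = 2, seed = config$seed)
  if (emit("structure")) {
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
    write_tsv(data.frame(axis = seq_along(pca$values),
                         eigenvalue = pca$values,
                         tw = c(pca$twstats,
                                rep(NA, length(pca$values) -
                                      length(pca$twstats))),
                         p = c(pca$pvalues,
                               rep(NA, length(pca$values) -
                                     length(pca$pvalues)))),
              file.path(out_dir, "pca_eigenvalues.tsv"))
    write_tsv(data.frame(sample = rownames(adm$Q), as.data.frame(adm$Q)),
              file.path(out_dir, "admixture_q.tsv"))
  }

  thin <- thin_snps(fpanel, per_chrom = 250)
  pairs <- pairwise_ld(thin, max_distance = ld_max_dist)
  decay <- ld_decay(pairs, bin_width = window_size)
  blocks <- haplotype_blocks(thin, max_span = 20000)
  if (emit("ld")) {
    write_tsv(cbind(decay$profile,
                    decay_distance = decay$decay_distance),
              file.path(out_dir, "ld_decay.tsv"))
    write_tsv(blocks, file.path(out_dir, "haplotype_blocks.tsv"))
  }

  summary <- build_summary(fpanel, ann, cnv_calls, pav_states, pav_regions)
  manifest <- list(package = "chickdiv",
                   version = as.character(utils::packageVersion("chickdiv")),
                   seed = config$seed,
                   config = config[setdiff(names(config),
                                           c("sweeps", "balancing",
                                             "cnv_events", "pav_events"))],
                   window_size = window_size,
                   scan_min_span = scan_min_span,
                   ld_max_dist = ld_max_dist,
                   admixture_k = admixture_k,
                   stages = names(stage_files),
                   rerun_from = if (first_missing <= length(stage_files))
                     names(stage_files)[first_missing] else "none")
  if (emit("report")) {
    write_tsv(summary, file.path(out_dir, "summary.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}

#' Thin a panel to at most a fixed number of SNPs per chromosome
#' @param panel a \code{panel_genotypes}.
#' @param per_chrom maximum SNPs kept per chromosome (evenly spaced).
#' @return the thinned panel.
#' @export
thin_snps <- function(panel, per_chrom = 250) {
  keep <- unlist(lapply(split(seq_len(nrow(panel$sites)),
                              panel$sites$chrom), function(idx) {
    idx <- idx[panel$sites$class[idx] == "SNP"]
    if (length(idx) <= per_chrom) idx
    else idx[round(seq(1, length(idx), length.out = per_chrom))]
  }))
  subset_sites(panel, sort(unname(keep)))
}
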