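# Writers/readers for the standard interchange formats: VCF 4.2 (GT:DP),
# per-sample bedGraph depth tracks, GFF3 gene models, TSV sample sheets and
# the JSON truth ledger.  Internally everything is 0-based half-open;
# conversion to 1-based happens only here.

#' Write a panel to VCF 4.2
#'
#' Emits one record per site with GT:DP per sample, via \pkg{vcfR}.
#'
#' @param panel a \code{panel_genotypes}.
#' @param file output path; \code{vcfR::write.vcf} gzip-compresses, so use a
#'   \code{.vcf.gz} suffix.
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, file) {
  s <- panel$sites
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(s), nrow(panel$samples))
  ok <- !is.na(panel$geno)
  gt[ok] <- gt_code[panel$geno[ok] + 1L]
  gt <- matrix(paste(gt, ifelse(is.na(panel$depth), ".", panel$depth),
                     sep = ":"),
               nrow(s), nrow(panel$samples))
  colnames(gt) <- panel$samples$sample
  gt <- cbind(FORMAT = "GT:DP", gt)
  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos + 1L),
               ID = NA_character_, REF = s$ref, ALT = s$alt,
               QUAL = NA_character_, FILTER = "PASS", INFO = NA_character_)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = file)
  invisible(file)
}

#' Read a panel back from a VCF written by [write_panel_vcf()]
#'
#' @param file VCF path.
#' @param samples optional sample-sheet data frame (sample, market_type,
#'   release_period, country); defaults to bare ids from the VCF header.
#' @return a \code{panel_genotypes}.
#' @export
read_panel_vcf <- function(file, samples = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  cls <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = ref, alt = alt, class = cls,
                      stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(sample = colnames(gt), market_type = NA,
                          release_period = NA, country = NA,
                          stringsAsFactors = FALSE)
  structure(list(sites = sites, geno = unname(dose) + 0L,
                 depth = unname(dp), samples = samples),
            class = "panel_genotypes")
}

#' Write per-sample depth tracks as bedGraph
#'
#' One 4-column file (chrom, start, end, mean depth) per sample.
#'
#' @param track a \code{depth_track}.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_depth_bedgraph <- function(track, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(track$samples, ".depth.bedGraph"))
  for (k in seq_along(track$samples)) {
    df <- cbind(track$bins, depth = track$depth[, k])
    utils::write.table(df, paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read per-sample bedGraph depth tracks
#'
#' @param paths bedGraph files, one per sample; sample ids are taken from the
#'   file names.
#' @return a \code{depth_track}.
#' @export
read_depth_bedgraph <- function(paths) {
  dfs <- lapply(paths, utils::read.table, sep = "\t",
                col.names = c("chrom", "start", "end", "depth"))
  bins <- dfs[[1]][, c("chrom", "start", "end")]
  depth <- vapply(dfs, `[[`, numeric(nrow(bins)), "depth")
  ids <- sub("\\.depth\\.bedGraph$", "", basename(paths))
  colnames(depth) <- ids
  structure(list(bins = bins, depth = depth, samples = ids,
                 mean_depth = colMeans(depth),
                 bin_width = max(bins$end - bins$start)),
            class = "depth_track")
}

#' Write gene models as GFF3
#'
#' @param genome a \code{genome_model}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_genome_gff3 <- function(genome, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ci in seq_len(nrow(genome$chromosomes)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       genome$chromosomes$name[ci],
                       genome$chromosomes$length[ci]), con)
  g <- genome$genes
  if (nrow(g)) {
    gl <- sprintf("%s\tchickdiv\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
    cd <- genome$cds
    # phase: cumulative CDS length modulo 3 in transcription order
    ph <- unlist(lapply(split(cd, cd$gene_id), function(d) {
      d <- d[order(d$start), ]
      lens <- d$end - d$start
      if (d$strand[1] == "-")
        rev(cumsum(c(0, utils::head(rev(lens), -1))) %% 3)
      else
        cumsum(c(0, utils::head(lens, -1))) %% 3
    }), use.names = FALSE)
    co <- cd[order(cd$gene_id, cd$start), ]
    cl <- sprintf("%s\tchickdiv\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                  co$chrom, co$start + 1L, co$end, co$strand, ph,
                  co$gene_id, co$gene_id)
    writeLines(c(gl, cl), con)
  }
  invisible(file)
}

#' Write the sample sheet as TSV
#' @param samples sample-sheet data frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(samples, file) {
  utils::write.table(samples, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the planted-truth ledger as JSON
#' @param truth a \code{truth_set}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  x <- lapply(unclass(truth), function(el) {
    if (is.matrix(el)) as.data.frame(el) else el
  })
  jsonlite::write_json(x, file, dataframe = "columns", na = "null",
                       digits = NA)
  invisible(file)
}

#' Read a panel configuration from YAML
#'
#' @param file YAML file whose keys match the arguments of
#'   [panel_config()]; table-valued keys (sweeps, balancing, cnv_events,
#'   pav_events) are given as lists of records.
#' @return a \code{panel_config}.
#' @export
read_panel_config <- function(file) {
  y <- yaml::read_yaml(file)
  for (k in c("sweeps", "balancing", "cnv_events", "pav_events"))
    if (!is.null(y[[k]]))
      y[[k]] <- do.call(rbind, lapply(y[[k]], function(r)
        as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                      stringsAsFactors = FALSE)))
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  do.call(panel_config, y)
}
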