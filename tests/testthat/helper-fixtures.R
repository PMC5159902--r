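# Hand-built fixtures: panels, genomes and depth tracks assembled directly
# from matrices, independent of the simulator.

make_panel <- function(geno, chrom = "Ca1", pos = NULL, ref = "A",
                       alt = "G", class = "SNP", depth = NULL,
                       market = NULL, rp = NULL) {
  geno <- as.matrix(geno)
  ns <- nrow(geno); n <- ncol(geno)
  if (is.null(pos)) pos <- seq(0, by = 100, length.out = ns)
  if (is.null(depth)) depth <- matrix(10, ns, n)
  ids <- sprintf("v%02d", seq_len(n))
  colnames(geno) <- ids
  structure(list(
    sites = data.frame(chrom = rep_len(chrom, ns), pos = pos,
                       ref = rep_len(ref, ns), alt = rep_len(alt, ns),
                       class = rep_len(class, ns), stringsAsFactors = FALSE),
    geno = geno, depth = depth,
    samples = data.frame(sample = ids,
                         market_type = rep_len(market %||%
                                                 c("desi", "kabuli"), n),
                         release_period = rep_len(rp %||%
                                                    c("RP1", "RP2", "RP3"),
                                                  n),
                         country = "India", stringsAsFactors = FALSE)),
    class = "panel_genotypes")
}

# genome with explicitly supplied sequence and gene tables
make_genome <- function(seqs, genes = NULL, cds = NULL) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(name = names(seqs), length = nchar(seqs),
                             stringsAsFactors = FALSE),
    seq = Biostrings::DNAStringSet(seqs),
    genes = genes %||% empty, cds = cds %||% empty),
    class = "genome_model")
}

make_track <- function(depth, chrom = "Ca1", bin_width = 1000) {
  depth <- as.matrix(depth)
  nb <- nrow(depth)
  ids <- colnames(depth) %||% sprintf("v%02d", seq_len(ncol(depth)))
  colnames(depth) <- ids
  st <- seq(0L, by = bin_width, length.out = nb)
  structure(list(bins = data.frame(chrom = rep_len(chrom, nb), start = st,
                                   end = st + bin_width,
                                   stringsAsFactors = FALSE),
                 depth = depth, samples = ids,
                 mean_depth = colMeans(depth), bin_width = bin_width),
            class = "depth_track")
}
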