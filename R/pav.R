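# Presence/absence variation from depth coverage: per-sample region calls
# against fractions of the genome-wide mean depth, group-level consensus
# flags, and gene-loss calling with the cross-sample absence spectrum.

# mean depth of a sample over a region, bin-overlap weighted
region_mean_depth <- function(track, sample, chrom, start, end) {
  hit <- track$bins$chrom == chrom & track$bins$start < end &
    track$bins$end > start
  if (!any(hit)) stop_config("region has no depth bins")
  w <- interval_overlap(track$bins$start[hit], track$bins$end[hit],
                        start, end)
  sum(track$depth[hit, sample] * w) / sum(w)
}

#' Presence/absence state of one sample in one region
#'
#' Deletion-type region: absent when mean region depth is strictly below
#' 10\% of the sample's genome-wide mean; otherwise present.
#' Insertion-type region: present when mean region depth is strictly above
#' 50\% of the genome-wide mean; otherwise absent.
#'
#' @param track a \code{depth_track}.
#' @param sample sample id.
#' @param chrom,start,end region coordinates (0-based half-open).
#' @param region_class "deletion" or "insertion".
#' @return "present" or "absent".
#' @export
call_sample_pav <- function(track, sample, chrom, start, end,
                            region_class = c("deletion", "insertion")) {
  region_class <- match.arg(region_class)
  d <- region_mean_depth(track, sample, chrom, start, end)
  gw <- track$mean_depth[[sample]]
  if (region_class == "deletion") {
    if (d < 0.10 * gw) "absent" else "present"
  } else {
    if (d > 0.50 * gw) "present" else "absent"
  }
}

#' Presence/absence states for a set of regions across all samples
#'
#' @param track a \code{depth_track}.
#' @param regions data frame with chrom, start, end and class
#'   ("deletion" or "insertion").
#' @return character matrix (regions x samples) of states.
#' @export
call_pav_matrix <- function(track, regions) {
  out <- matrix(NA_character_, nrow(regions), length(track$samples),
                dimnames = list(NULL, track$samples))
  for (r in seq_len(nrow(regions)))
    for (sm in track$samples)
      out[r, sm] <- call_sample_pav(track, sm, regions$chrom[r],
                                    regions$start[r], regions$end[r],
                                    regions$class[r])
  out
}

#' Group-level PAV consensus flags
#'
#' A group is flagged for a region when strictly more than
#' \code{min_count} of its samples carry the region's variant state
#' (absent for deletion-type regions, present for insertion-type regions).
#' Groups smaller than \code{min_count + 1} can never be flagged and are
#' reported with a warning.
#'
#' @param states character matrix from [call_pav_matrix()].
#' @param regions the matching region data frame (for the class column).
#' @param grouping factor/vector of group labels, one per sample column.
#' @param min_count flag threshold; default 3 ("more than three samples").
#' @return logical matrix (regions x groups).
#' @export
call_group_pav <- function(states, regions, grouping, min_count = 3) {
  grouping <- factor(grouping)
  if (length(grouping) != ncol(states) || any(is.na(grouping)))
    stop_config("every sample needs a group label")
  small <- table(grouping) <= min_count
  if (any(small))
    warning("group(s) of size <= ", min_count, " can never be flagged: ",
            paste(names(which(small)), collapse = ", "))
  variant_state <- ifelse(regions$class == "deletion", "absent", "present")
  out <- vapply(levels(grouping), function(g) {
    cols <- grouping == g
    rowSums(states[, cols, drop = FALSE] == variant_state) > min_count
  }, logical(nrow(states)))
  if (nrow(states) == 1) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL,
                                                       levels(grouping)))
  out
}

#' Gene-loss calling from depth coverage
#'
#' A gene is lost in a sample when the fraction of its span covered at
#' depth >= 1 (approximated bin-wise: a bin counts as covered when its mean
#' depth is at least 1) is strictly below 10\%.  Also returns the
#' cross-sample absence spectrum: number of genes absent in exactly 1, 2, 3
#' and more than 3 samples.
#'
#' @param track a \code{depth_track}.
#' @param genome a \code{genome_model}.
#' @return list with \code{lost} (logical genes x samples matrix),
#'   \code{coverage} (covered-fraction matrix) and \code{spectrum}.
#' @export
call_gene_loss <- function(track, genome) {
  genes <- genome$genes
  ns <- length(track$samples)
  cov <- matrix(NA_real_, nrow(genes), ns,
                dimnames = list(genes$gene_id, track$samples))
  for (gi in seq_len(nrow(genes))) {
    hit <- track$bins$chrom == genes$chrom[gi] &
      track$bins$start < genes$end[gi] & track$bins$end > genes$start[gi]
    if (!any(hit)) stop_config("gene %s outside track coverage",
                               genes$gene_id[gi])
    w <- interval_overlap(track$bins$start[hit], track$bins$end[hit],
                          genes$start[gi], genes$end[gi])
    covered <- track$depth[hit, , drop = FALSE] >= 1
    cov[gi, ] <- colSums(covered * w) / sum(w)
  }
  lost <- cov < 0.10
  n_lost <- rowSums(lost)
  spectrum <- c(`1` = sum(n_lost == 1), `2` = sum(n_lost == 2),
                `3` = sum(n_lost == 3), `>3` = sum(n_lost > 3))
  list(lost = lost, coverage = cov, spectrum = spectrum)
}
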