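#' Filter markers by minor allele frequency
#'
#' Allele frequencies are computed over non-missing calls; a heterozygous
#' genotype contributes one copy of each allele. The minor allele frequency
#' is the frequency of the second most common nucleotide at the marker.
#' Markers are retained when MAF is strictly greater than `min_maf`;
#' all-missing (and monomorphic, MAF = 0) markers are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf retention threshold in \[0, 0.5\] (strict `>`).
#' @return a `genotype_matrix` with the retained markers. The number and ids
#'   of dropped markers are attached as attribute `"dropped"`.
#' @export
filter_maf <- function(gm, min_maf = 0.10) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  cnt <- allele_count_table(gm$calls)
  tot <- rowSums(cnt)
  srt <- apply(cnt, 1L, function(x) sort(x, decreasing = TRUE)[2L])
  maf <- ifelse(tot > 0, srt / tot, NA_real_)
  keep <- !is.na(maf) & maf > min_maf
  n_allmiss <- sum(tot == 0)
  if (n_allmiss > 0)
    message("filter_maf: dropped ", n_allmiss, " all-missing marker(s)")
  out <- subset_gm(gm, markers = keep)
  attr(out, "dropped") <- gm$markers$id[!keep]
  out
}

#' Prune markers in complete LD with a close upstream marker
#'
#' Reduced-representation sequencing calls several SNPs on one short read
#' tag; these carry no independent information. Scanning each sequence left
#' to right, a marker is removed when a retained marker strictly less than
#' `window_bp` upstream has an identical genotype pattern on the samples
#' where both are non-missing and the two are in complete LD (r² = 1, which
#' for identical patterns requires at least two distinct genotypes among the
#' shared samples). The leftmost marker of each redundant run is kept, so the
#' operation is idempotent.
#'
#' @param gm a [genotype_matrix()] (markers sorted, as the class guarantees).
#' @param window_bp window in bp (strict `<`; default 64).
#' @return a `genotype_matrix` with redundant markers removed; dropped ids in
#'   attribute `"dropped"`.
#' @export
prune_redundant_markers <- function(gm, window_bp = 64) {
  mk <- gm$markers
  calls <- gm$calls
  n <- nrow(mk)
  keep <- rep(TRUE, n)
  miss <- gt_is_missing(calls)
  for (i in seq_len(n)[-1]) {
    j <- i - 1L
    while (j >= 1L && mk$chrom[j] == mk$chrom[i] &&
           mk$pos[i] - mk$pos[j] < window_bp) {
      if (keep[j]) {
        shared <- !miss[i, ] & !miss[j, ]
        if (any(shared)) {
          gi <- calls[i, shared]
          gj <- calls[j, shared]
          if (all(gi == gj) && length(unique(gi)) >= 2L) {
            keep[i] <- FALSE
            break
          }
        }
      }
      j <- j - 1L
    }
  }
  if (any(!keep))
    message("prune_redundant_markers: removed ", sum(!keep),
            " marker(s) in complete LD within ", window_bp, " bp")
  out <- subset_gm(gm, markers = keep)
  attr(out, "dropped") <- mk$id[!keep]
  out
}
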