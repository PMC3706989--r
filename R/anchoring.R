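# Raw 0/1 introgression call matrix (NA elsewhere) from a trio_call_matrix.
raw_call_matrix <- function(tcm) {
  m <- matrix(NA_real_, nrow(tcm$calls), ncol(tcm$calls),
              dimnames = list(tcm$markers$id, tcm$pairs$sc))
  m[tcm$calls == CALL_PRESENT] <- 1
  m[tcm$calls == CALL_ABSENT] <- 0
  m
}

#' Unanchored SNPs eligible for LD-based placement
#'
#' Placement by correlation is only informative for contig SNPs with enough
#' raw introgression calls and a non-trivial introgression frequency:
#' eligibility requires at least `min_calls` present/absent calls and a raw
#' present fraction (present / (present + absent)) of at least `min_freq`.
#'
#' @param tcm a [classify_all()] result including unanchored-contig markers.
#' @param min_calls minimum raw call count (default 20, `>=`).
#' @param min_freq minimum raw present fraction (default 0.10, `>=`).
#' @return character vector of eligible marker ids.
#' @export
eligible_unanchored <- function(tcm, min_calls = 20, min_freq = 0.10) {
  un <- is_unanchored_chrom(tcm$markers$chrom)
  if (!any(un)) return(character())
  calls <- tcm$calls[un, , drop = FALSE]
  n_pres <- rowSums(calls == CALL_PRESENT, na.rm = TRUE)
  n_abs <- rowSums(calls == CALL_ABSENT, na.rm = TRUE)
  n <- n_pres + n_abs
  ok <- n >= min_calls & ifelse(n > 0, n_pres / n, 0) >= min_freq
  tcm$markers$id[un][ok]
}

#' Anchor contig SNPs to chromosomes by LD of introgression calls
#'
#' Backcross-derived lines carry introgressions in long blocks, so raw 0/1
#' introgression calls are correlated over long physical distances; an
#' unanchored SNP therefore correlates most strongly with anchored SNPs near
#' its true location. For each unanchored SNP, the squared Pearson
#' correlation (r²) against every anchored SNP is computed on
#' pairwise-complete calls with at least `min_calls` overlap; all anchored
#' SNPs tied for the maximum r² (within `tie_tol`) are reported, and a
#' chromosome is assigned when the tied set lies on a single chromosome.
#'
#' @param tcm a [classify_all()] result.
#' @param snps unanchored marker ids to place (default
#'   [eligible_unanchored()] with default thresholds).
#' @param min_calls minimum pairwise-complete overlap for a valid r².
#' @param tie_tol numeric tolerance for r² ties (default 1e-12).
#' @return data.frame of class `anchor_placement`: `snp_id`, `contig`,
#'   `assigned_chrom` (NA when ambiguous), `best_r2`, `n_tied`,
#'   `tied_span_bp` (span of tied positions when on one chromosome),
#'   `best_snp` (one top anchored SNP id), `n_calls`, `unique`.
#' @export
anchor_by_r2 <- function(tcm, snps = NULL, min_calls = 20, tie_tol = 1e-12) {
  if (is.null(snps)) snps <- eligible_unanchored(tcm, min_calls = min_calls)
  raw <- raw_call_matrix(tcm)
  un <- is_unanchored_chrom(tcm$markers$chrom)
  anch_idx <- which(!un)
  if (!length(anch_idx)) stop("no anchored markers to place against")
  ui <- match(snps, tcm$markers$id)
  if (anyNA(ui)) stop("unknown snp id")
  x <- t(raw[ui, , drop = FALSE])
  y <- t(raw[anch_idx, , drop = FALSE])
  suppressWarnings({
    r <- cor(x, y, use = "pairwise.complete.obs")
  })
  r2 <- r^2
  overlap <- crossprod(!is.na(x), !is.na(y))
  r2[overlap < min_calls] <- NA_real_
  amk <- tcm$markers[anch_idx, , drop = FALSE]
  res <- lapply(seq_along(snps), function(k) {
    rk <- r2[k, ]
    if (all(is.na(rk))) {
      return(data.frame(snp_id = snps[k],
                        contig = tcm$markers$chrom[ui[k]],
                        assigned_chrom = NA_character_, best_r2 = NA_real_,
                        n_tied = 0L, tied_span_bp = NA_real_,
                        best_snp = NA_character_, n_calls = 0L,
                        unique = FALSE, stringsAsFactors = FALSE))
    }
    best <- max(rk, na.rm = TRUE)
    tied <- which(!is.na(rk) & rk >= best - tie_tol)
    chs <- unique(amk$chrom[tied])
    uniq <- length(chs) == 1L
    data.frame(snp_id = snps[k],
               contig = tcm$markers$chrom[ui[k]],
               assigned_chrom = if (uniq) chs else NA_character_,
               best_r2 = best,
               n_tied = length(tied),
               tied_span_bp = if (uniq)
                 diff(range(amk$pos[tied])) else NA_real_,
               best_snp = amk$id[tied[which.max(rk[tied])]],
               n_calls = max(overlap[k, tied]),
               unique = uniq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("anchor_placement", "data.frame")
  out
}

#' Write anchor placements as TSV
#'
#' @param placements an [anchor_by_r2()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  write.table(as.data.frame(placements), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
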