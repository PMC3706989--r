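#' Build a donor consensus genotype from replicate libraries
#'
#' Sequencing the donor line several times (replicate libraries, possibly from
#' several seed sources) yields redundant but noisy calls. Libraries whose
#' mean pairwise non-missing concordance with the other libraries falls below
#' `min_concordance` are dropped first (a library prepared from a deviant seed
#' source or a failed prep shows up as a global outlier). The consensus call
#' at each marker is then the majority call among the remaining non-missing
#' calls; markers whose majority call is heterozygous, tied between two
#' homozygous calls, or supported by less than `majority` of the non-missing
#' calls are set missing, so every non-missing consensus call is homozygous.
#'
#' @param gm a [genotype_matrix()] whose samples are the donor replicate
#'   libraries.
#' @param min_concordance drop libraries with mean pairwise concordance below
#'   this fraction (default 0.8).
#' @param majority minimum fraction of non-missing calls the majority
#'   homozygous call must reach (default 0.8).
#' @return an object of class `donor_consensus`: list with `calls` (named
#'   character vector, one genotype or `"NN"` per marker), `markers`,
#'   `n_libraries_used`, `dropped_libraries` (data.frame with reasons).
#' @export
consensus_donor <- function(gm, min_concordance = 0.8, majority = 0.8) {
  calls <- gm$calls
  n <- ncol(calls)
  if (n < 1L) stop("no donor libraries in input")
  dropped <- data.frame(library = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  if (n >= 2L) {
    conc <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ok <- !gt_is_missing(calls[, i]) & !gt_is_missing(calls[, j])
        conc[i, j] <- conc[j, i] <-
          if (any(ok)) mean(calls[ok, i] == calls[ok, j]) else NA_real_
      }
    }
    mean_conc <- rowMeans(conc, na.rm = TRUE)
    low <- !is.na(mean_conc) & mean_conc < min_concordance
    if (any(low)) {
      dropped <- data.frame(
        library = colnames(calls)[low],
        reason = sprintf("mean pairwise concordance %.3f < %.3f",
                         mean_conc[low], min_concordance),
        stringsAsFactors = FALSE)
      keep <- !low
    }
  }
  if (!any(keep)) stop("all donor libraries dropped for low concordance")
  calls <- calls[, keep, drop = FALSE]

  cons <- apply(calls, 1L, function(row) {
    row <- row[!gt_is_missing(row)]
    if (!length(row)) return(GT_MISSING)
    tab <- sort(table(row), decreasing = TRUE)
    top <- names(tab)[1L]
    if (gt_is_het(top)) return(GT_MISSING)
    if (length(tab) > 1L && tab[2L] == tab[1L]) return(GT_MISSING)
    if (tab[1L] / length(row) < majority) return(GT_MISSING)
    top
  })
  names(cons) <- gm$markers$id
  structure(list(calls = cons,
                 markers = gm$markers,
                 n_libraries_used = sum(keep),
                 dropped_libraries = dropped),
            class = "donor_consensus")
}

#' @export
print.donor_consensus <- function(x, ...) {
  cat("donor_consensus: ", length(x$calls), " markers, ",
      x$n_libraries_used, " libraries used, ",
      nrow(x$dropped_libraries), " dropped\n", sep = "")
  cat("  missing consensus calls: ",
      sprintf("%.1f%%", 100 * mean(x$calls == GT_MISSING)), "\n", sep = "")
  invisible(x)
}
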