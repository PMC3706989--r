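#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor prcomp quantile rbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

GT_MISSING <- "NN"

#' Test whether a sequence name denotes an unanchored contig
#'
#' Anchored chromosomes sort first in a [genotype_matrix()]; sequences whose
#' name matches this pattern (contigs, scaffolds, super-contigs) sort after
#' them and are the candidates for LD-based anchoring.
#'
#' @param chrom character vector of sequence names.
#' @param pattern regular expression identifying unanchored sequences.
#' @return logical vector.
#' @export
is_unanchored_chrom <- function(chrom,
                                pattern = getOption("introgmap.contig_pattern",
                                                    "^(contig|scaffold|super)")) {
  grepl(pattern, chrom, ignore.case = TRUE)
}

# Normalize genotype strings: uppercase, single letters doubled ("A" -> "AA"),
# alleles in alphabetical order, anything containing N (or NA) -> "NN".
normalize_gt <- function(g) {
  g <- toupper(as.character(g))
  g[is.na(g) | g == "" | g == "-" | g == "--"] <- GT_MISSING
  one <- !is.na(g) & nchar(g) == 1L
  g[one] <- paste0(g[one], g[one])
  a1 <- substr(g, 1L, 1L)
  a2 <- substr(g, 2L, 2L)
  swap <- a2 < a1
  g[swap] <- paste0(a2[swap], a1[swap])
  g[grepl("N", g, fixed = TRUE)] <- GT_MISSING
  g
}

gt_is_missing <- function(g) is.na(g) | g == GT_MISSING
gt_is_het <- function(g) !gt_is_missing(g) & substr(g, 1L, 1L) != substr(g, 2L, 2L)

# Sort order of markers: anchored chromosomes first (natural numeric order of
# names where possible), unanchored contigs after, position ascending within.
marker_order <- function(markers) {
  unanch <- is_unanchored_chrom(markers$chrom)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", markers$chrom)))
  num[is.na(num)] <- Inf
  order(unanch, num, markers$chrom, markers$pos)
}

#' Construct a genotype matrix
#'
#' The central container of the package: a set of biallelic markers with
#' genome coordinates and a markers-by-samples matrix of genotype calls coded
#' as two-letter nucleotide strings (`"AA"`, `"AG"`, ...; `"NN"` = missing).
#' Markers are stored sorted by (chromosome, position) with unanchored
#' contigs after the anchored chromosomes.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`.
#' @param calls character matrix of genotype strings, one row per marker (in
#'   the order of `markers`), one column per sample; column names are sample
#'   identifiers.
#' @return An object of class `genotype_matrix` with elements `markers`,
#'   `samples` and `calls`.
#' @export
genotype_matrix <- function(markers, calls) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos") %in% names(markers)))
  if (is.null(markers$ref)) markers$ref <- NA_character_
  if (is.null(markers$alt)) markers$alt <- NA_character_
  markers <- markers[, c("id", "chrom", "pos", "ref", "alt")]
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(markers))
    stop("calls has ", nrow(calls), " rows but there are ",
         nrow(markers), " markers")
  if (is.null(colnames(calls)))
    stop("calls must have sample identifiers as column names")
  if (anyDuplicated(colnames(calls)))
    stop("duplicated sample id: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("duplicated marker id: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (any(markers$pos < 1, na.rm = TRUE))
    stop("marker positions must be >= 1 (1-based bp)")
  calls[] <- normalize_gt(calls)
  ord <- marker_order(markers)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  rownames(markers) <- NULL
  rownames(calls) <- markers$id
  structure(list(markers = markers,
                 samples = colnames(calls),
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nu <- sum(is_unanchored_chrom(x$markers$chrom))
  cat("genotype_matrix: ", nrow(x$markers), " markers x ",
      length(x$samples), " samples\n", sep = "")
  cat("  sequences: ", length(unique(x$markers$chrom)),
      " (", nu, " markers on unanchored contigs)\n", sep = "")
  cat("  missing calls: ",
      sprintf("%.1f%%", 100 * mean(gt_is_missing(x$calls))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by markers and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param markers marker ids, logical mask, or indices; `NULL` keeps all.
#' @param samples sample ids, logical mask, or indices; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, markers = NULL, samples = NULL) {
  mi <- seq_len(nrow(gm$markers))
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, gm$markers$id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id")
  }
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id: ",
                        paste(samples[is.na(match(samples, gm$samples))],
                              collapse = ", "))
  }
  genotype_matrix(gm$markers[mi, , drop = FALSE],
                  gm$calls[mi, si, drop = FALSE])
}

# Per-marker nucleotide allele counts over non-missing genotypes.
# Returns a markers x 4 matrix of counts of A, C, G, T (het counts 1 each).
allele_count_table <- function(calls) {
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  a1[gt_is_missing(calls)] <- NA
  a2[gt_is_missing(calls)] <- NA
  nts <- c("A", "C", "G", "T")
  out <- matrix(0L, nrow = nrow(calls), ncol = 4L,
                dimnames = list(rownames(calls), nts))
  for (nt in nts) {
    out[, nt] <- rowSums(a1 == nt, na.rm = TRUE) + rowSums(a2 == nt, na.rm = TRUE)
  }
  out
}

# Alt-allele dosage matrix (0/1/2; NA for missing or off-type alleles),
# relative to markers$ref / markers$alt.
alt_dosage <- function(gm) {
  a1 <- substr(gm$calls, 1L, 1L)
  a2 <- substr(gm$calls, 2L, 2L)
  refm <- matrix(gm$markers$ref, nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  altm <- matrix(gm$markers$alt, nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ok <- (a1 == refm | a1 == altm) & (a2 == refm | a2 == altm)
  d <- (a1 == altm) + (a2 == altm)
  d[!ok | gt_is_missing(gm$calls)] <- NA
  dimnames(d) <- dimnames(gm$calls)
  d
}
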