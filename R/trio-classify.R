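# Integer codes used inside a trio_call_matrix. Missing is NA.
CALL_ABSENT <- 0L
CALL_PRESENT <- 1L
CALL_UNEXPECTED <- 2L
CALL_NONINFORMATIVE <- 3L
CALL_LEVELS <- c("absent", "present", "unexpected", "noninformative")

code_to_label <- function(code) {
  out <- CALL_LEVELS[code + 1L]
  out[is.na(code)] <- "missing"
  out
}

# Vectorized classifier on genotype strings; returns integer codes (NA =
# missing). The scientific content of the trio comparison lives here.
classify_codes <- function(sc, ep, donor) {
  bad <- gt_is_missing(sc) | gt_is_missing(ep) | gt_is_missing(donor) |
    gt_is_het(sc) | gt_is_het(ep) | gt_is_het(donor)
  a_sc <- substr(sc, 1L, 1L)
  a_ep <- substr(ep, 1L, 1L)
  a_dn <- substr(donor, 1L, 1L)
  out <- rep(CALL_UNEXPECTED, length(sc))
  out[a_sc == a_ep & a_ep == a_dn] <- CALL_NONINFORMATIVE
  out[a_sc == a_dn & a_dn != a_ep] <- CALL_PRESENT
  out[a_sc == a_ep & a_ep != a_dn] <- CALL_ABSENT
  out[bad] <- NA_integer_
  out
}

#' Classify one genotype trio into an introgression call
#'
#' For a marker genotyped in a converted line (SC), its exotic progenitor
#' (EP) and the elite donor, a homozygous trio has four outcomes: all three
#' alleles equal (no polymorphism, non-informative); SC shares the donor
#' allele and not the EP allele (introgression present); SC shares the EP
#' allele and not the donor allele (introgression absent); or the SC allele
#' is found in neither parent (unexpected — evidence of contamination,
#' pedigree error or drift). Any heterozygous or missing member of the trio
#' yields a missing call.
#'
#' @param sc,ep,donor genotype strings (`"AA"`, `"AG"`, `"NN"`; vectors are
#'   recycled to a common length).
#' @return character vector in `c("present", "absent", "unexpected",
#'   "noninformative", "missing")`.
#' @export
classify_trio <- function(sc, ep, donor) {
  n <- max(length(sc), length(ep), length(donor))
  code_to_label(classify_codes(normalize_gt(rep_len(sc, n)),
                               normalize_gt(rep_len(ep, n)),
                               normalize_gt(rep_len(donor, n))))
}

new_trio_call_matrix <- function(markers, pairs, calls) {
  rownames(calls) <- markers$id
  colnames(calls) <- pairs$sc
  structure(list(markers = markers, pairs = pairs, calls = calls),
            class = "trio_call_matrix")
}

#' Classify every marker for every SC-EP pair
#'
#' Applies [classify_trio()] element-wise across a marker-by-pair grid,
#' using the donor consensus genotype at each marker.
#'
#' @param sc [genotype_matrix()] of converted (SC) lines.
#' @param ep [genotype_matrix()] of exotic progenitor (EP) lines.
#' @param donor a [consensus_donor()] result (or a named genotype vector).
#' @param pairing data.frame with columns `sc`, `ep` mapping each SC line to
#'   its progenitor; must reference samples present in the two matrices.
#' @return an object of class `trio_call_matrix`: `markers`, `pairs` and an
#'   integer `calls` matrix (0 = absent, 1 = present, 2 = unexpected,
#'   3 = non-informative, NA = missing).
#' @export
classify_all <- function(sc, ep, donor, pairing) {
  stopifnot(is.data.frame(pairing), all(c("sc", "ep") %in% names(pairing)))
  if (anyDuplicated(pairing$sc) || anyDuplicated(pairing$ep))
    stop("pairing must be a bijection between SC and EP samples")
  miss_sc <- setdiff(pairing$sc, sc$samples)
  if (length(miss_sc))
    stop("unpaired or unknown SC sample: ", paste(miss_sc, collapse = ", "))
  miss_ep <- setdiff(pairing$ep, ep$samples)
  if (length(miss_ep))
    stop("unpaired or unknown EP sample: ", paste(miss_ep, collapse = ", "))
  dcalls <- if (inherits(donor, "donor_consensus")) donor$calls else donor
  ids <- sc$markers$id
  if (!identical(ids, ep$markers$id) || !all(ids %in% names(dcalls)))
    stop("sc, ep and donor must share the same marker list")
  scm <- sc$calls[, pairing$sc, drop = FALSE]
  epm <- ep$calls[, pairing$ep, drop = FALSE]
  dn <- matrix(dcalls[ids], nrow = length(ids), ncol = nrow(pairing))
  calls <- matrix(classify_codes(scm, epm, dn),
                  nrow = length(ids), ncol = nrow(pairing))
  new_trio_call_matrix(sc$markers, pairing[, c("sc", "ep"), drop = FALSE],
                       calls)
}

#' @export
print.trio_call_matrix <- function(x, ...) {
  tab <- call_class_counts(x)
  cat("trio_call_matrix: ", nrow(x$markers), " markers x ",
      nrow(x$pairs), " pairs\n", sep = "")
  cat("  ", paste(sprintf("%s %.1f%%", names(tab),
                          100 * tab / sum(tab)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tabulate introgression call classes
#'
#' @param tcm a [classify_all()] result.
#' @return named integer vector of counts over the five classes.
#' @export
call_class_counts <- function(tcm) {
  code <- tcm$calls
  c(present = sum(code == CALL_PRESENT, na.rm = TRUE),
    absent = sum(code == CALL_ABSENT, na.rm = TRUE),
    unexpected = sum(code == CALL_UNEXPECTED, na.rm = TRUE),
    noninformative = sum(code == CALL_NONINFORMATIVE, na.rm = TRUE),
    missing = sum(is.na(code)))
}

unexpected_fraction <- function(calls, margin) {
  unx <- apply(calls == CALL_UNEXPECTED, margin, sum, na.rm = TRUE)
  inf <- apply(calls == CALL_PRESENT | calls == CALL_ABSENT, margin, sum,
               na.rm = TRUE)
  denom <- unx + inf
  ifelse(denom > 0, unx / denom, NA_real_)
}

#' Discard markers with an excess of unexpected genotypes
#'
#' The unexpected fraction of a marker is the number of unexpected calls over
#' the number of informative (present/absent) plus unexpected calls. Markers
#' strictly above `max_unexpected` are removed; markers with no such calls
#' are retained and flagged uninformative.
#'
#' @param tcm a [classify_all()] result.
#' @param max_unexpected removal threshold (strict `>`; default 0.20).
#' @return list with `tcm` (filtered), `retained`, `removed` (marker ids) and
#'   `report` (data.frame: per-chromosome removal counts).
#' @export
marker_qc <- function(tcm, max_unexpected = 0.20) {
  if (nrow(tcm$markers) == 0L) stop("empty trio_call_matrix")
  frac <- unexpected_fraction(tcm$calls, 1L)
  remove <- !is.na(frac) & frac > max_unexpected
  tab <- table(tcm$markers$chrom[remove])
  report <- data.frame(chrom = names(tab), n_removed = as.integer(tab),
                       stringsAsFactors = FALSE)
  out <- new_trio_call_matrix(tcm$markers[!remove, , drop = FALSE],
                              tcm$pairs,
                              tcm$calls[!remove, , drop = FALSE])
  list(tcm = out,
       retained = tcm$markers$id[!remove],
       removed = tcm$markers$id[remove],
       uninformative = tcm$markers$id[is.na(frac)],
       unexpected_fraction = setNames(frac, tcm$markers$id),
       report = report)
}

#' Discard SC-EP pairs with an excess of unexpected genotypes
#'
#' Same statistic as [marker_qc()] with per-pair denominators; intended to be
#' applied after marker-level QC. A high per-pair unexpected fraction marks a
#' pedigree or sample-handling error for that pair.
#'
#' @param tcm a [classify_all()] result (normally `marker_qc(...)$tcm`).
#' @param max_unexpected removal threshold (strict `>`; default 0.10).
#' @return list with `tcm` (filtered), `retained`, `removed` (SC ids) and
#'   `unexpected_fraction` per pair.
#' @export
pair_qc <- function(tcm, max_unexpected = 0.10) {
  if (nrow(tcm$pairs) == 0L) stop("empty trio_call_matrix")
  frac <- unexpected_fraction(tcm$calls, 2L)
  remove <- !is.na(frac) & frac > max_unexpected
  out <- new_trio_call_matrix(tcm$markers,
                              tcm$pairs[!remove, , drop = FALSE],
                              tcm$calls[, !remove, drop = FALSE])
  list(tcm = out,
       retained = tcm$pairs$sc[!remove],
       removed = tcm$pairs$sc[remove],
       unexpected_fraction = setNames(frac, tcm$pairs$sc))
}
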