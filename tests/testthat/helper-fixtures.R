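# Small fixture builders shared across test files.

# Genotype matrix from a character matrix of two-letter calls; markers are
# placed on one chromosome at the given positions unless chrom is a vector.
make_gm <- function(calls, pos = NULL, chrom = "Chr01",
                    ref = NULL, alt = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  m <- nrow(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(ids)) ids <- paste0("m", seq_len(m))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_matrix(
    data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    calls)
}

# HapMap-style TSV text for a genotype matrix, written to a temp file.
write_tmp_hapmap <- function(gm) {
  f <- tempfile(fileext = ".hmp.txt")
  write_hapmap(gm, f)
  f
}

# A trio_call_matrix built directly from an integer code matrix
# (0 absent, 1 present, 2 unexpected, 3 noninformative, NA missing).
make_tcm <- function(codes, pos = NULL, chrom = "Chr01", pair_ids = NULL) {
  codes <- as.matrix(codes)
  m <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(pair_ids)) pair_ids <- paste0("SC", seq_len(ncol(codes)))
  markers <- data.frame(id = paste0("m", seq_len(m)),
                        chrom = rep_len(chrom, m), pos = pos,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  pairs <- data.frame(sc = pair_ids, ep = sub("SC", "EP", pair_ids),
                      stringsAsFactors = FALSE)
  introgmap:::new_trio_call_matrix(markers, pairs,
                                   matrix(as.integer(codes), m,
                                          ncol(codes)))
}

# A score_matrix built directly from a numeric matrix (NA = undefined).
make_sm <- function(scores, pos = NULL, chrom = "Chr01") {
  scores <- as.matrix(scores)
  m <- nrow(scores)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  markers <- data.frame(id = paste0("m", seq_len(m)),
                        chrom = rep_len(chrom, m), pos = pos,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  pairs <- data.frame(sc = paste0("SC", seq_len(ncol(scores))),
                      ep = paste0("EP", seq_len(ncol(scores))),
                      stringsAsFactors = FALSE)
  dimnames(scores) <- list(markers$id, pairs$sc)
  structure(list(markers = markers, pairs = pairs, scores = scores,
                 provenance = matrix("observed", m, ncol(scores))),
            class = "score_matrix")
}

# Independent reference for the trio classification rule, written set-wise:
# alleles of the SC genotype against the allele sets of the parents.
oracle_classify <- function(sc, ep, dn) {
  gts <- list(sc = sc, ep = ep, dn = dn)
  al <- lapply(gts, function(g) strsplit(g, "")[[1]])
  if (any(vapply(al, function(a) "N" %in% a, logical(1)))) return("missing")
  if (any(vapply(al, function(a) a[1] != a[2], logical(1)))) return("missing")
  s <- al$sc[1]; e <- al$ep[1]; d <- al$dn[1]
  if (s == e && e == d) return("noninformative")
  if (s == d && d != e) return("present")
  if (s == e && e != d) return("absent")
  "unexpected"
}

# All homozygous + het + missing genotype codes over a nucleotide alphabet.
all_genotypes <- function(nts = c("A", "C", "G", "T")) {
  homs <- paste0(nts, nts)
  hets <- combn(nts, 2, FUN = function(x) paste0(x[1], x[2]))
  c(homs, hets, "NN")
}
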