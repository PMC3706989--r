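#' Impute fractional introgression scores from flanking markers
#'
#' Present/absent calls become scores 1/0. Unexpected, non-informative and
#' missing calls are treated as missing and filled per pair and chromosome:
#' a cell at position p between nearest informative flanks (pL, sL) and
#' (pR, sR) gets the distance-weighted mean
#' `(sL * (pR - p) + sR * (p - pL)) / (pR - pL)`; cells before the first or
#' after the last informative marker on a chromosome take that nearest
#' marker's score; chromosomes with no informative marker for a pair stay
#' undefined and are excluded from downstream denominators.
#'
#' @param tcm a [classify_all()] result (after QC).
#' @return an object of class `score_matrix`: `markers`, `pairs`, numeric
#'   `scores` in \[0, 1\] (NA = undefined) and a `provenance` matrix with
#'   values `"observed"`, `"interpolated"`, `"edge"`, `"undefined"`.
#' @export
impute_scores <- function(tcm) {
  code <- tcm$calls
  obs <- matrix(NA_real_, nrow(code), ncol(code))
  obs[code == CALL_PRESENT] <- 1
  obs[code == CALL_ABSENT] <- 0
  pos <- tcm$markers$pos
  chrom <- tcm$markers$chrom
  scores <- obs
  prov <- matrix("undefined", nrow(code), ncol(code))
  prov[!is.na(obs)] <- "observed"
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    p <- pos[rows]
    for (j in seq_len(ncol(code))) {
      y <- obs[rows, j]
      filled <- fill_linear(p, y)
      scores[rows, j] <- filled$y
      prov[rows[filled$kind == 1L], j] <- "interpolated"
      prov[rows[filled$kind == 2L], j] <- "edge"
    }
  }
  dimnames(scores) <- dimnames(prov) <- list(tcm$markers$id, tcm$pairs$sc)
  structure(list(markers = tcm$markers, pairs = tcm$pairs,
                 scores = scores, provenance = prov),
            class = "score_matrix")
}

# Linear fill of NA values of y observed at increasing positions p.
# kind: 0 observed/undefined, 1 interpolated, 2 edge-filled.
fill_linear <- function(p, y) {
  kind <- integer(length(y))
  obs <- which(!is.na(y))
  if (length(obs) == 0L) return(list(y = y, kind = kind))
  miss <- which(is.na(y))
  if (length(miss) == 0L) return(list(y = y, kind = kind))
  po <- p[obs]
  so <- y[obs]
  idx <- findInterval(p[miss], po)
  left_edge <- idx == 0L
  right_edge <- idx == length(obs) & !left_edge
  interior <- !left_edge & !right_edge
  out <- numeric(length(miss))
  out[left_edge] <- so[1L]
  out[right_edge] <- so[length(so)]
  if (any(interior)) {
    iL <- idx[interior]
    pL <- po[iL]; pR <- po[iL + 1L]
    sL <- so[iL]; sR <- so[iL + 1L]
    pm <- p[miss][interior]
    w <- ifelse(pR > pL, (sL * (pR - pm) + sR * (pm - pL)) / (pR - pL),
                (sL + sR) / 2)
    out[interior] <- w
  }
  y[miss] <- out
  kind[miss[interior]] <- 1L
  kind[miss[!interior]] <- 2L
  list(y = y, kind = kind)
}

#' @export
print.score_matrix <- function(x, ...) {
  tab <- table(factor(x$provenance,
                      c("observed", "interpolated", "edge", "undefined")))
  cat("score_matrix: ", nrow(x$markers), " markers x ", nrow(x$pairs),
      " pairs\n  ", paste(sprintf("%s %.1f%%", names(tab),
                                  100 * tab / sum(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Genome-wide introgression frequency track
#'
#' Per marker, the mean of the defined scores across the selected pairs,
#' expressed in percent. The number of pairs contributing (pairs with a
#' defined score at the marker) is recorded so alternative denominator
#' conventions remain recoverable.
#'
#' @param sm an [impute_scores()] result.
#' @param pairs optional subset of SC ids (default: all pairs).
#' @return a `frequency_track` data.frame: `chrom`, `pos`, `value` (percent,
#'   NA where no pair contributes), `n_pairs`.
#' @export
introgression_frequency <- function(sm, pairs = NULL) {
  s <- sm$scores
  if (!is.null(pairs)) {
    si <- match(pairs, sm$pairs$sc)
    if (anyNA(si)) stop("unknown pair id")
    s <- s[, si, drop = FALSE]
  }
  if (ncol(s) == 0L) stop("no pairs selected")
  n <- rowSums(!is.na(s))
  value <- ifelse(n > 0, 100 * rowMeans(s, na.rm = TRUE), NA_real_)
  frequency_track(sm$markers$chrom, sm$markers$pos, value, n)
}

frequency_track <- function(chrom, pos, value, n_pairs = NA_integer_) {
  structure(data.frame(chrom = chrom, pos = pos, value = value,
                       n_pairs = n_pairs, stringsAsFactors = FALSE),
            class = c("frequency_track", "data.frame"))
}

#' Write a per-marker track as a BED-like TSV
#'
#' Output intervals are 0-based half-open (`start0 = pos - 1`, `end0 = pos`),
#' converted from the package's internal 1-based marker positions; a header
#' comment states the convention.
#'
#' @param track a `frequency_track` (or any data.frame with `chrom`, `pos`,
#'   `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# chrom\tstart0\tend0\tvalue ",
                    "(0-based half-open intervals)"), con)
  out <- data.frame(chrom = track$chrom,
                    start0 = format(track$pos - 1, scientific = FALSE,
                                    trim = TRUE),
                    end0 = format(track$pos, scientific = FALSE, trim = TRUE),
                    value = track$value)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a score matrix as TSV (marker rows, pair columns)
#'
#' @param sm an [impute_scores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sm, path) {
  out <- data.frame(marker = sm$markers$id, chrom = sm$markers$chrom,
                    pos = sm$markers$pos, sm$scores, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
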