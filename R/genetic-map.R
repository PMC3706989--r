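#' Build a genetic map for the simulator
#'
#' Defaults emulate a sorghum-like genome: 10 chromosomes of 1.6 Morgans
#' each (16 Morgans total) with a constant physical-to-genetic rate, so
#' marker bp positions map linearly to genetic positions.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length genetic length per chromosome in Morgans (scalar or
#'   vector of length `n_chrom`).
#' @param markers_per_chrom evenly spaced markers per chromosome.
#' @param bp_per_morgan physical bp per Morgan (default 4e7, i.e. 64 Mb per
#'   1.6-Morgan chromosome).
#' @return an object of class `genetic_map`: list with `chroms` (data.frame:
#'   `chrom`, `length_morgan`, `length_bp`) and `markers` (data.frame:
#'   `id`, `chrom`, `pos` in bp, `gpos` in Morgans).
#' @export
genetic_map <- function(n_chrom = 10, chrom_length = 1.6,
                        markers_per_chrom = 500, bp_per_morgan = 4e7) {
  chrom_length <- rep_len(chrom_length, n_chrom)
  stopifnot(all(chrom_length >= 0), markers_per_chrom >= 1)
  names <- sprintf("Chr%02d", seq_len(n_chrom))
  chroms <- data.frame(chrom = names,
                       length_morgan = chrom_length,
                       length_bp = chrom_length * bp_per_morgan,
                       stringsAsFactors = FALSE)
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    g <- seq(0, chrom_length[c],
             length.out = markers_per_chrom + 2L)[-c(1L, markers_per_chrom + 2L)]
    if (chrom_length[c] == 0)
      g <- rep(0, markers_per_chrom)
    data.frame(id = sprintf("S%02d_%09.0f", c,
                            pmax(1, round(g * bp_per_morgan))),
               chrom = names[c],
               pos = pmax(1, round(g * bp_per_morgan)),
               gpos = g,
               stringsAsFactors = FALSE)
  }))
  rownames(markers) <- NULL
  structure(list(chroms = chroms, markers = markers,
                 bp_per_morgan = bp_per_morgan),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map: ", nrow(x$chroms), " chromosomes, ",
      sum(x$chroms$length_morgan), " Morgans, ",
      nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}
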