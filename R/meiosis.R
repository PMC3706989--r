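# Haplotypes are run-length representations of parental origin along one
# chromosome: list(ends = increasing segment end positions in Morgans (the
# last equals the chromosome length), labs = integer origin label per
# segment; 1 = donor, 0 = recurrent/exotic parent).

hap_const <- function(L, lab) list(ends = L, labs = lab)

# One meiotic product of a single chromosome under the Haldane model:
# crossover count ~ Poisson(L Morgans), positions uniform, no interference,
# starting haplotype chosen with probability 1/2.
gamete_chrom <- function(h1, h2, L) {
  k <- rpois(1L, L)
  start1 <- runif(1L) < 0.5
  if (k == 0L) return(if (start1) h1 else h2)
  if (!start1) { tmp <- h1; h1 <- h2; h2 <- tmp }
  xo <- runif(k, 0, L)
  if (k > 1L) xo <- sort.int(xo, method = "quick")
  if (length(h1$labs) == 1L && length(h2$labs) == 1L) {
    if (h1$labs == h2$labs) return(h1)
    return(list(ends = c(xo, L),
                labs = rep_len(c(h1$labs, h2$labs), k + 1L)))
  }
  ends <- sort.int(c(h1$ends, h2$ends, xo), method = "quick")
  ends <- ends[c(ends[-1L] != ends[-length(ends)], TRUE)]
  m <- length(ends)
  mid <- (c(0, ends[-m]) + ends) * 0.5
  on1 <- (findInterval(mid, xo) %% 2L) == 0L
  lab <- integer(m)
  if (any(on1)) lab[on1] <- h1$labs[findInterval(mid[on1], h1$ends) + 1L]
  if (!all(on1)) lab[!on1] <- h2$labs[findInterval(mid[!on1], h2$ends) + 1L]
  keep <- c(lab[-1L] != lab[-m], TRUE)
  list(ends = ends[keep], labs = lab[keep])
}

#' Sample one gamete from a diploid individual
#'
#' Meiosis under the Haldane model: per chromosome, a Poisson(length in
#' Morgans) number of crossovers at uniform genetic positions with no
#' interference, and a fair choice of starting haplotype. The recombination
#' fraction between loci d Morgans apart is therefore (1 - exp(-2d)) / 2.
#'
#' @param ind a diploid individual: list with elements `h1`, `h2`, each a
#'   list (one per chromosome) of origin-labelled haplotypes as produced by
#'   the simulator.
#' @param map a [genetic_map()].
#' @return a list of haplotypes, one per chromosome.
#' @export
sample_gamete <- function(ind, map) {
  L <- map$chroms$length_morgan
  lapply(seq_along(L), function(c)
    gamete_chrom(ind$h1[[c]], ind$h2[[c]], L[c]))
}

hap_label_at <- function(hap, gpos) {
  hap$labs[pmin(findInterval(gpos, hap$ends) + 1L, length(hap$labs))]
}

ind_is_donor_hom <- function(ind, targets) {
  for (t in seq_len(nrow(targets))) {
    c <- targets$chrom_index[t]
    g <- targets$gpos[t]
    if (hap_label_at(ind$h1[[c]], g) != 1L ||
        hap_label_at(ind$h2[[c]], g) != 1L) return(FALSE)
  }
  TRUE
}

#' Simulate one conversion (backcross) line
#'
#' Two crossing schemes are available. `"f2_backcross"` reproduces the
#' conversion program: an F1 between donor and the recurrent exotic parent,
#' then `B` cycles of (self to an F2, select an F2 individual homozygous for
#' the donor allele at every target locus, backcross the selected plant to
#' the recurrent parent), and a final selfing in which a target-homozygous
#' offspring is selected and residual heterozygosity is resolved at random
#' (one further meiosis), yielding an inbred line represented by a single
#' haplotype. `"backcross"` is the classical plain chain — F1 followed by
#' `B` straight backcrosses, then the same final selfing — the scheme under
#' which the textbook donor-fraction moments for backcross-derived inbreds
#' are stated; it supports no selection targets.
#'
#' Either way the expected donor genome fraction of the final line without
#' selection is (1/2)^(B+1).
#'
#' @param map a [genetic_map()].
#' @param B number of backcross generations (default 4).
#' @param targets NULL, or data.frame with columns `chrom` (name or index)
#'   and `gpos` (Morgans) of loci kept donor-homozygous by selection.
#' @param max_tries resampling bound for each selection step.
#' @param scheme `"f2_backcross"` (default) or `"backcross"` (see above).
#' @return list of haplotypes (one per chromosome) of the final inbred line.
#' @export
simulate_bc_line <- function(map, B = 4, targets = NULL, max_tries = 1e4,
                             scheme = c("f2_backcross", "backcross")) {
  scheme <- scheme[1L]
  if (!scheme %in% c("f2_backcross", "backcross"))
    stop("unknown scheme: ", scheme)
  nc <- nrow(map$chroms)
  L <- map$chroms$length_morgan
  donor <- lapply(seq_len(nc), function(c) hap_const(L[c], 1L))
  ep <- lapply(seq_len(nc), function(c) hap_const(L[c], 0L))
  targets <- normalize_targets(targets, map)
  sel <- !is.null(targets) && nrow(targets) > 0L
  if (sel && scheme == "backcross")
    stop("selection targets require the f2_backcross scheme")
  cur <- list(h1 = donor, h2 = ep) # F1
  for (b in seq_len(B)) {
    picked <- if (scheme == "f2_backcross")
      select_offspring(cur, cur, map, targets, sel, max_tries) else cur
    cur <- list(h1 = sample_gamete(picked, map), h2 = ep) # backcross to EP
  }
  fin <- select_offspring(cur, cur, map, targets, sel, max_tries)
  # resolve residual heterozygosity: one further meiosis fixes each
  # segregating segment at random
  sample_gamete(fin, map)
}

select_offspring <- function(p1, p2, map, targets, sel, max_tries) {
  for (i in seq_len(max_tries)) {
    off <- list(h1 = sample_gamete(p1, map), h2 = sample_gamete(p2, map))
    if (!sel || ind_is_donor_hom(off, targets)) return(off)
  }
  stop("selection unsatisfiable: no offspring carried the donor allele ",
       "at all target loci within ", max_tries, " tries")
}

normalize_targets <- function(targets, map) {
  if (is.null(targets) || nrow(as.data.frame(targets)) == 0L) return(NULL)
  targets <- as.data.frame(targets)
  if (!all(c("chrom", "gpos") %in% names(targets)))
    stop("targets needs columns chrom, gpos")
  ci <- if (is.numeric(targets$chrom)) as.integer(targets$chrom)
        else match(as.character(targets$chrom), map$chroms$chrom)
  if (anyNA(ci) || any(ci < 1L | ci > nrow(map$chroms)))
    stop("unknown target chromosome")
  if (any(targets$gpos < 0 | targets$gpos > map$chroms$length_morgan[ci]))
    stop("target gpos outside chromosome")
  data.frame(chrom_index = ci, gpos = targets$gpos,
             group = if (is.null(targets$group)) NA_character_
                     else as.character(targets$group),
             stringsAsFactors = FALSE)
}

#' Donor-genome fraction of a simulated line
#'
#' Map-length-weighted proportion of the genome carrying the donor origin
#' label.
#'
#' @param hap list of haplotypes (one per chromosome), e.g. from
#'   [simulate_bc_line()].
#' @param map a [genetic_map()].
#' @return numeric fraction in \[0, 1\].
#' @export
donor_fraction <- function(hap, map) {
  tot <- sum(map$chroms$length_morgan)
  if (tot == 0) return(NA_real_)
  don <- vapply(hap, function(h) {
    starts <- c(0, h$ends[-length(h$ends)])
    sum((h$ends - starts)[h$labs == 1L])
  }, numeric(1))
  sum(don) / tot
}

#' Expected donor-genome fraction after backcrossing
#'
#' After an F1 and `B` backcrosses to the recurrent parent, the expected
#' donor fraction without selection is (1/2)^(B+1): 3.125\% for B = 4,
#' i.e. roughly 3\%.
#'
#' @param B number of backcross generations.
#' @return expected fraction in \[0, 1\].
#' @export
expected_donor_fraction <- function(B = 4) 0.5^(B + 1)

# True 0/1 donor state at each map marker for one line haplotype.
truth_states <- function(hap, map) {
  mk <- map$markers
  unlist(lapply(seq_len(nrow(map$chroms)), function(c) {
    g <- mk$gpos[mk$chrom == map$chroms$chrom[c]]
    as.integer(hap_label_at(hap[[c]], g) == 1L)
  }), use.names = FALSE)
}

# Donor tracts of one line haplotype, in bp.
truth_tracts <- function(hap, map) {
  out <- lapply(seq_len(nrow(map$chroms)), function(c) {
    h <- hap[[c]]
    don <- which(h$labs == 1L)
    if (!length(don)) return(NULL)
    starts <- c(0, h$ends[-length(h$ends)])
    data.frame(chrom = map$chroms$chrom[c],
               start = pmax(1, round(starts[don] * map$bp_per_morgan)),
               end = round(h$ends[don] * map$bp_per_morgan),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
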