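#' Configuration for the conversion-program simulator
#'
#' Defaults describe the emulated study conditions: 100 SC-EP pairs, four
#' backcross generations on a 10-chromosome, 16-Morgan genome with 500
#' markers per chromosome, 66\% missing and 0.3\% heterozygous calls, and a
#' low scattered unexpected-genotype rate.
#'
#' @param n_pairs number of SC-EP pairs.
#' @param B backcross generations (default 4).
#' @param targets NULL or data.frame with `chrom` (name or index), `gpos`
#'   (Morgans) and optional `group` (restricting selection to pairs of that
#'   subpopulation) of loci kept donor-homozygous by selection.
#' @param n_chrom,chrom_length,markers_per_chrom,bp_per_morgan passed to
#'   [genetic_map()].
#' @param divergence fraction of markers polymorphic between donor and the
#'   progenitor pool.
#' @param ep_freq length-2 range; at a polymorphic marker the frequency of
#'   the non-donor allele in the progenitor pool is drawn uniformly from it.
#'   `c(1, 1)` makes every polymorphic marker informative in every pair (a
#'   fully divergent cross).
#' @param groups NULL (one population) or list with `sizes` (integer vector)
#'   and optional `labels` and `fst` (Balding-Nichols differentiation of the
#'   progenitor subpopulations, default 0.15).
#' @param noise list of rates: `missing`, `het`, `unexpected` (scalar or one
#'   per pair), `mode` (`"scattered"`, `"segmental"` or `"pair_swap"`).
#' @param n_donor_libs replicate donor libraries to emit.
#' @param donor_lib_error per-call error rate in donor replicate libraries.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pairs = 100, B = 4, targets = NULL,
                       n_chrom = 10, chrom_length = 1.6,
                       markers_per_chrom = 500, bp_per_morgan = 4e7,
                       divergence = 0.8, ep_freq = c(0.1, 1), groups = NULL,
                       noise = list(missing = 0.66, het = 0.003,
                                    unexpected = 0.02, mode = "scattered"),
                       n_donor_libs = 8, donor_lib_error = 0.002,
                       seed = 1L) {
  noise <- utils::modifyList(list(missing = 0, het = 0, unexpected = 0,
                                  mode = "scattered"), as.list(noise))
  stopifnot(n_pairs >= 1, B >= 0, divergence >= 0, divergence <= 1,
            length(ep_freq) == 2, all(ep_freq >= 0), all(ep_freq <= 1),
            noise$missing >= 0, noise$missing <= 1,
            noise$het >= 0, noise$het <= 1,
            all(noise$unexpected >= 0), all(noise$unexpected <= 1))
  if (!is.null(groups)) {
    if (is.null(groups$labels))
      groups$labels <- c("C", "D", "GK")[seq_along(groups$sizes)]
    if (is.null(groups$fst)) groups$fst <- 0.15
    if (sum(groups$sizes) != n_pairs)
      stop("group sizes must sum to n_pairs")
  }
  structure(list(n_pairs = n_pairs, B = B, targets = targets,
                 n_chrom = n_chrom, chrom_length = chrom_length,
                 markers_per_chrom = markers_per_chrom,
                 bp_per_morgan = bp_per_morgan,
                 divergence = divergence, ep_freq = ep_freq,
                 groups = groups, noise = noise,
                 n_donor_libs = n_donor_libs,
                 donor_lib_error = donor_lib_error,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a conversion program: donor, progenitor and converted trios
#'
#' Generates, for each pair, an exotic progenitor (EP) line drawn from a
#' (possibly structured) progenitor pool, runs the backcross conversion
#' scheme of [simulate_bc_line()] against a fixed elite donor, and emits
#' noise-free genotype matrices at the map markers together with the ground
#' truth (per-line donor tracts and per-marker 0/1 introgression states).
#' Apply [add_noise()] afterwards to emulate missingness, heterozygous calls
#' and unexpected genotypes.
#'
#' @param config a [sim_config()].
#' @return an object of class `trio_dataset`: `donor`, `ep`, `sc`
#'   ([genotype_matrix()]s; the donor matrix holds replicate libraries),
#'   `pairing` (data.frame `sc`, `ep`, `group`), `truth` (list: `states`
#'   markers x pairs 0/1 matrix, `tracts` data.frame), `map`, `config`.
#' @export
simulate_conversion <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(config$seed)
  map <- genetic_map(config$n_chrom, config$chrom_length,
                     config$markers_per_chrom, config$bp_per_morgan)
  mk <- map$markers
  M <- nrow(mk)
  n <- config$n_pairs
  nts <- c("A", "C", "G", "T")
  d_all <- sample(nts, M, replace = TRUE)
  e_all <- vapply(d_all, function(d) sample(setdiff(nts, d), 1L), "")
  poly <- runif(M) < config$divergence
  # freq of the non-donor allele in the progenitor pool
  q <- ifelse(poly, runif(M, config$ep_freq[1], config$ep_freq[2]), 0)

  if (is.null(config$groups)) {
    group <- rep(NA_character_, n)
    qg <- matrix(q, M, 1L)
    gidx <- rep(1L, n)
  } else {
    group <- rep(config$groups$labels, config$groups$sizes)
    f <- config$groups$fst
    ng <- length(config$groups$sizes)
    qg <- matrix(0, M, ng)
    a <- q * (1 - f) / f
    b <- (1 - q) * (1 - f) / f
    for (g in seq_len(ng)) {
      qg[poly, g] <- stats::rbeta(sum(poly), a[poly], b[poly])
    }
    gidx <- rep(seq_len(ng), config$groups$sizes)
  }

  sc_ids <- sprintf("SC%04d", seq_len(n))
  ep_ids <- sprintf("EP%04d", seq_len(n))
  # inbred EP lines: one allele draw per marker, doubled
  ep_allele <- matrix("", M, n)
  for (j in seq_len(n)) {
    ep_allele[, j] <- ifelse(runif(M) < qg[, gidx[j]], e_all, d_all)
  }

  targets <- config$targets
  states <- matrix(0L, M, n)
  tracts <- vector("list", n)
  for (j in seq_len(n)) {
    tj <- targets
    if (!is.null(tj) && !is.null(tj$group)) {
      keep <- is.na(tj$group) | tj$group == group[j]
      tj <- tj[keep, , drop = FALSE]
    }
    hap <- simulate_bc_line(map, config$B, tj)
    states[, j] <- truth_states(hap, map)
    tr <- truth_tracts(hap, map)
    if (!is.null(tr) && nrow(tr)) {
      tr$line <- sc_ids[j]
      tracts[[j]] <- tr
    }
  }
  tracts <- do.call(rbind, tracts[!vapply(tracts, is.null, logical(1))])

  sc_allele <- ifelse(states == 1L, d_all, ep_allele)
  markers <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos,
                        ref = d_all, alt = ifelse(poly, e_all, NA_character_),
                        stringsAsFactors = FALSE)
  sc_gm <- genotype_matrix(markers, matrix(paste0(sc_allele, sc_allele),
                                           M, n, dimnames = list(NULL, sc_ids)))
  ep_gm <- genotype_matrix(markers, matrix(paste0(ep_allele, ep_allele),
                                           M, n, dimnames = list(NULL, ep_ids)))
  lib_ids <- sprintf("DONOR_L%02d", seq_len(config$n_donor_libs))
  dcall <- matrix(paste0(d_all, d_all), M, config$n_donor_libs,
                  dimnames = list(NULL, lib_ids))
  if (config$donor_lib_error > 0) {
    err <- runif(length(dcall)) < config$donor_lib_error
    dcall[err] <- paste0(e_all, e_all)[(which(err) - 1L) %% M + 1L]
  }
  donor_gm <- genotype_matrix(markers, dcall)
  dimnames(states) <- list(mk$id, sc_ids)
  structure(list(donor = donor_gm, ep = ep_gm, sc = sc_gm,
                 pairing = data.frame(sc = sc_ids, ep = ep_ids,
                                      group = group,
                                      stringsAsFactors = FALSE),
                 truth = list(states = states, tracts = tracts),
                 map = map, config = config),
            class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat("trio_dataset: ", nrow(x$sc$markers), " markers, ",
      nrow(x$pairing), " SC-EP pairs, ", length(x$donor$samples),
      " donor libraries\n", sep = "")
  cat("  mean true donor fraction (marker-weighted): ",
      sprintf("%.2f%%", 100 * mean(x$truth$states)), "\n", sep = "")
  invisible(x)
}

#' Inject missingness, heterozygous calls and unexpected genotypes
#'
#' Noise is applied per cell, in the order unexpected, then heterozygous,
#' then missing. Unexpected genotypes affect only SC cells at markers where
#' the donor and that pair's progenitor carry different alleles; the SC call
#' is replaced by a third allele, emulating the observed signatures:
#' `"scattered"` (independent cells — drift-like), `"segmental"` (one
#' contiguous block per pair — a foreign introgression) or `"pair_swap"`
#' (progenitor identities of the affected pairs are cyclically swapped — a
#' clerical error). Heterozygous and missing noise hit all three matrices.
#'
#' @param ds a [simulate_conversion()] result.
#' @param missing per-cell missing rate.
#' @param het per-cell heterozygous-call rate.
#' @param unexpected scalar rate, or one rate per pair.
#' @param mode unexpected-genotype mode (see above).
#' @param seed integer seed (default: derived from the dataset's config).
#' @return a `trio_dataset` with modified genotype matrices; the truth is
#'   unchanged (it describes the pre-noise state).
#' @export
add_noise <- function(ds, missing = 0, het = 0, unexpected = 0,
                      mode = c("scattered", "segmental", "pair_swap"),
                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "trio_dataset"))
  if (is.null(seed)) seed <- ds$config$seed + 1000003L
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  mk <- ds$sc$markers
  M <- nrow(mk)
  n <- nrow(ds$pairing)
  unexpected <- rep_len(unexpected, n)

  if (any(unexpected > 0)) {
    sc <- ds$sc$calls
    epc <- ds$ep$calls[, ds$pairing$ep, drop = FALSE]
    dall <- mk$ref # the donor carries the ref allele throughout
    if (mode == "pair_swap") {
      swap <- which(unexpected > 0)
      if (length(swap) >= 2L) {
        ds$pairing$ep[swap] <- ds$pairing$ep[c(swap[-1L], swap[1L])]
      }
    } else {
      for (j in seq_len(n)) {
        if (unexpected[j] <= 0) next
        ep_a <- substr(epc[, j], 1L, 1L)
        polyj <- which(ep_a != dall)
        if (!length(polyj)) next
        if (mode == "scattered") {
          hit <- polyj[runif(length(polyj)) < unexpected[j]]
        } else { # segmental: one contiguous block of the polymorphic cells
          k <- round(unexpected[j] * length(polyj))
          if (k < 1L) next
          start <- sample.int(length(polyj) - k + 1L, 1L)
          hit <- polyj[seq(start, start + k - 1L)]
        }
        if (!length(hit)) next
        third <- vapply(hit, function(i)
          sample(setdiff(nts, c(dall[i], ep_a[i])), 1L), "")
        sc[hit, j] <- paste0(third, third)
      }
    }
    ds$sc <- genotype_matrix(mk, sc)
  }

  hit_cells <- function(gm, rate, make) {
    if (rate <= 0) return(gm)
    calls <- gm$calls
    idx <- which(runif(length(calls)) < rate)
    if (length(idx)) calls[idx] <- make(calls, idx)
    genotype_matrix(gm$markers, calls)
  }
  make_het <- function(calls, idx) {
    i <- (idx - 1L) %% nrow(calls) + 1L
    a <- substr(calls[idx], 1L, 1L)
    other <- ifelse(!is.na(mk$alt[i]) & a == mk$ref[i], mk$alt[i], mk$ref[i])
    other <- ifelse(other == a | is.na(other),
                    vapply(a, function(x) sample(setdiff(nts, x), 1L), ""),
                    other)
    normalize_gt(paste0(a, other))
  }
  make_miss <- function(calls, idx) GT_MISSING
  for (part in c("donor", "ep", "sc")) {
    gm <- ds[[part]]
    gm <- hit_cells(gm, het, make_het)
    gm <- hit_cells(gm, missing, make_miss)
    ds[[part]] <- gm
  }
  ds
}

#' Move simulated SNPs onto synthetic unanchored contigs
#'
#' Relabels small runs of consecutive markers as SNPs on unanchored contigs
#' (new sequence names `contig_###`, arbitrary local positions), recording
#' their true origin, so LD-based anchoring can be validated against a known
#' answer. When the dataset was simulated with selection targets, a fraction
#' of the contigs is drawn from near the targets, where introgression
#' frequencies are high enough for the SNPs to be eligible for placement.
#'
#' @param ds a [simulate_conversion()] result (noise may already be added).
#' @param n_contigs number of contigs to create.
#' @param snps_per_contig consecutive markers per contig.
#' @param near_targets_frac fraction of contigs sourced near a selection
#'   target (ignored without targets).
#' @param near_band genetic-distance band (Morgans) around a target from
#'   which near-target contigs are drawn. The default annulus excludes the
#'   fully swept core: SNPs there are introgressed in essentially every
#'   line, so their call pattern is shared by every swept locus genome-wide
#'   and carries no positional information.
#' @param seed integer seed.
#' @return list with `ds` (modified dataset) and `truth` (data.frame:
#'   `snp_id`, `contig`, `true_chrom`, `true_pos`).
#' @export
relocate_to_contigs <- function(ds, n_contigs = 30, snps_per_contig = 2,
                                near_targets_frac = 0.5,
                                near_band = c(0.02, 0.2),
                                seed = NULL) {
  stopifnot(inherits(ds, "trio_dataset"))
  if (is.null(seed)) seed <- ds$config$seed + 2000003L
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  map <- ds$map
  mkmap <- map$markers
  mk <- ds$sc$markers
  stopifnot(identical(mk$id, mkmap$id))
  M <- nrow(mk)
  targets <- normalize_targets(ds$config$targets, map)
  n_near <- if (is.null(targets)) 0L else round(near_targets_frac * n_contigs)
  starts <- integer(n_contigs)
  taken <- logical(M)
  pick_start <- function(cand) {
    cand <- cand[cand <= M - snps_per_contig + 1L]
    cand <- cand[!vapply(cand, function(s) {
      idx <- seq(s, s + snps_per_contig - 1L)
      any(taken[idx]) || length(unique(mk$chrom[idx])) != 1L
    }, logical(1))]
    if (!length(cand)) return(NA_integer_)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  for (k in seq_len(n_contigs)) {
    cand <- if (k <= n_near) {
      t <- targets[sample.int(nrow(targets), 1L), ]
      d <- abs(mkmap$gpos - t$gpos)
      which(mkmap$chrom == map$chroms$chrom[t$chrom_index] &
              d >= near_band[1] & d <= near_band[2])
    } else seq_len(M)
    s <- pick_start(cand)
    if (is.na(s)) s <- pick_start(seq_len(M))
    if (is.na(s)) stop("could not place contig ", k)
    starts[k] <- s
    taken[seq(s, s + snps_per_contig - 1L)] <- TRUE
  }
  truth <- do.call(rbind, lapply(seq_len(n_contigs), function(k) {
    idx <- seq(starts[k], starts[k] + snps_per_contig - 1L)
    data.frame(snp_id = mk$id[idx],
               contig = sprintf("contig_%03d", k),
               true_chrom = mk$chrom[idx],
               true_pos = mk$pos[idx],
               stringsAsFactors = FALSE)
  }))
  new_mk <- mk
  ti <- match(truth$snp_id, new_mk$id)
  new_mk$chrom[ti] <- truth$contig
  new_mk$pos[ti] <- 1000 * (ave(seq_along(ti), truth$contig,
                                FUN = seq_along))
  ord <- marker_order(new_mk)
  reorder_gm <- function(gm) genotype_matrix(new_mk, gm$calls)
  ds$sc <- reorder_gm(ds$sc)
  ds$ep <- reorder_gm(ds$ep)
  ds$donor <- reorder_gm(ds$donor)
  ds$truth$states <- ds$truth$states[ord, , drop = FALSE]
  list(ds = ds, truth = truth)
}
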