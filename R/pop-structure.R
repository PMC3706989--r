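#' Assign progenitor lines to subpopulations by PCA thresholds
#'
#' Runs a principal component analysis on alt-allele dosages (0/1/2, missing
#' filled with the marker mean) of the progenitor panel — the panel should
#' already be restricted to common markers (see [filter_maf()]) — and cuts
#' the first two PCs into three groups: `PC2 < pc2_split` is the guinea/kafir
#' (GK) group; otherwise `PC1 > pc1_split` is the caudatum (C) group, else
#' the durra (D) group.
#'
#' PC sign and scale are arbitrary across implementations, so each component
#' is canonicalized before the thresholds apply: its loading vector is
#' oriented so that the largest-magnitude loading is positive. The default
#' splits match one historical dataset and **must be recalibrated for new
#' data** (inspect the returned coordinates).
#'
#' @param ep [genotype_matrix()] of progenitor lines (MAF-filtered).
#' @param pc1_split,pc2_split thresholds on the canonicalized PCs.
#' @return an object of class `subpop_assignment`: data.frame `assignment`
#'   (`sample`, `PC1`, `PC2`, `group`), `group_sizes`, and the proportion of
#'   variance explained by the first two PCs.
#' @export
pca_assign <- function(ep, pc1_split = 0, pc2_split = -20) {
  if (length(ep$samples) < 3L) stop("need at least 3 samples for PCA")
  d <- alt_dosage(ep)
  mu <- rowMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d))
  d[idx] <- mu[(idx - 1L) %% nrow(d) + 1L]
  pc <- prcomp(t(d), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    load <- pc$rotation[, c]
    if (load[which.max(abs(load))] < 0) scores[, c] <- -scores[, c]
  }
  pc1 <- scores[, 1L]
  pc2 <- if (k >= 2L) scores[, 2L] else rep(0, length(pc1))
  group <- assign_from_pcs(pc1, pc2, pc1_split, pc2_split)
  assignment <- data.frame(sample = ep$samples, PC1 = pc1, PC2 = pc2,
                           group = group, stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(assignment = assignment,
                 group_sizes = table(factor(group, c("C", "D", "GK"))),
                 var_explained = ve[seq_len(k)],
                 pc1_split = pc1_split, pc2_split = pc2_split),
            class = "subpop_assignment")
}

#' Apply the subpopulation threshold rules to PC coordinates
#'
#' @param pc1,pc2 numeric vectors of PC coordinates.
#' @param pc1_split,pc2_split thresholds.
#' @return character vector in `c("C", "D", "GK")`.
#' @export
assign_from_pcs <- function(pc1, pc2, pc1_split = 0, pc2_split = -20) {
  ifelse(pc2 < pc2_split, "GK", ifelse(pc1 > pc1_split, "C", "D"))
}

#' @export
print.subpop_assignment <- function(x, ...) {
  cat("subpop_assignment: ", nrow(x$assignment), " samples -> ",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Hudson per-SNP Fst from alt-allele frequencies and haploid sample sizes.
fst_hudson_counts <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Per-SNP Hudson Fst between two panels
#'
#' For each shared marker the alt-allele frequency and the haploid allele
#' count (two alleles per non-missing genotype, heterozygotes contributing
#' one of each) are computed in each panel on pairwise-complete data, and the
#' Hudson estimator
#' \deqn{F_{st} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' is returned. Markers with fewer than two non-missing genotypes in either
#' panel, or monomorphic in both, are undefined (NA).
#'
#' @param panel_a,panel_b [genotype_matrix()] objects sharing a marker list
#'   (matched by marker id).
#' @return a `frequency_track` with `value` = Fst (unitless) and `n_pairs` =
#'   total haploid sample size used.
#' @export
hudson_fst <- function(panel_a, panel_b) {
  common <- intersect(panel_a$markers$id, panel_b$markers$id)
  if (!length(common)) stop("panels share no markers")
  a <- subset_gm(panel_a, markers = common)
  b <- subset_gm(panel_b, markers = common)
  da <- alt_dosage(a)
  db <- alt_dosage(b)
  na <- 2 * rowSums(!is.na(da))
  nb <- 2 * rowSums(!is.na(db))
  pa <- rowSums(da, na.rm = TRUE) / na
  pb <- rowSums(db, na.rm = TRUE) / nb
  fst <- fst_hudson_counts(pa, na, pb, nb)
  fst[na < 4 | nb < 4] <- NA_real_
  frequency_track(a$markers$chrom, a$markers$pos, fst,
                  as.integer(na + nb))
}

#' Subpopulation-wise introgression frequencies and their range
#'
#' @param sm an [impute_scores()] result.
#' @param groups character or factor vector of group labels, one per pair of
#'   `sm` (in order), or a named vector keyed by SC id.
#' @return list with one `frequency_track` per group (`tracks`), and `range`
#'   (a `frequency_track` of per-marker max minus min across groups, in
#'   percent).
#' @export
subpop_frequencies <- function(sm, groups) {
  groups <- resolve_groups(sm, groups)
  freqs <- group_freq_matrix(sm$scores, groups)
  tracks <- lapply(colnames(freqs), function(g)
    frequency_track(sm$markers$chrom, sm$markers$pos, freqs[, g],
                    sum(groups == g)))
  names(tracks) <- colnames(freqs)
  rng <- apply(freqs, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else max(x) - min(x)
  })
  list(tracks = tracks,
       range = frequency_track(sm$markers$chrom, sm$markers$pos, rng,
                               length(levels(groups))))
}

resolve_groups <- function(sm, groups) {
  if (!is.null(names(groups))) {
    groups <- groups[sm$pairs$sc]
    if (anyNA(groups)) stop("every pair must be assigned to a group")
  }
  if (length(groups) != nrow(sm$pairs))
    stop("groups must have one label per pair")
  groups <- if (is.factor(groups)) factor(groups, levels = levels(groups))
            else factor(as.character(groups))
  if (any(table(groups) == 0L)) stop("empty subpopulation group")
  groups
}

# markers x groups matrix of mean-score frequencies (percent), NA-aware.
group_freq_matrix <- function(scores, groups) {
  ind <- stats::model.matrix(~ g - 1, data.frame(g = groups))
  colnames(ind) <- levels(groups)
  s0 <- scores
  s0[is.na(s0)] <- 0
  num <- s0 %*% ind
  den <- (!is.na(scores)) %*% ind
  out <- 100 * num / den
  out[den == 0] <- NA_real_
  out
}

#' Permutation test for subpopulation-specific introgression
#'
#' Observed statistic: per marker, the range (max minus min) of the
#' introgression frequencies across subpopulations; per chromosome, the
#' maximum of that range over its markers. The null is built by repeatedly
#' permuting the pair-to-group labels (group sizes fixed), recording each
#' chromosome's maximum range. A chromosome's significance threshold is the
#' empirical (1 - alpha) quantile of its null; observed per-marker ranges
#' above their chromosome's threshold are flagged.
#'
#' @param sm an [impute_scores()] result.
#' @param groups group labels as in [subpop_frequencies()].
#' @param n_perm number of permutations (default 200).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; the result is fully reproducible given it.
#' @return an object of class `permutation_result`: `observed` (track of
#'   per-marker ranges), `chrom_stats` (data.frame with per-chromosome
#'   observed max, threshold, flag), `significant` (marker ids), `null`
#'   (n_perm x chromosomes matrix), plus `n_perm`, `alpha`, `seed`.
#' @export
permutation_range_test <- function(sm, groups, n_perm = 200, alpha = 0.05,
                                   seed = 1L) {
  if (n_perm < 20) warning("n_perm < 20: null quantile will be unstable")
  groups <- resolve_groups(sm, groups)
  chrom <- sm$markers$chrom
  chroms <- unique(chrom)
  chrom_f <- factor(chrom, levels = chroms)
  range_of <- function(freqs) {
    fmax <- do.call(pmax, c(as.data.frame(freqs), na.rm = TRUE))
    fmin <- do.call(pmin, c(as.data.frame(freqs), na.rm = TRUE))
    r <- fmax - fmin
    r[rowSums(!is.na(freqs)) < 2L] <- NA_real_
    r
  }
  obs_range <- range_of(group_freq_matrix(sm$scores, groups))
  obs_max <- tapply(obs_range, chrom_f, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  null <- matrix(NA_real_, n_perm, length(chroms),
                 dimnames = list(NULL, chroms))
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample(groups)
    r <- range_of(group_freq_matrix(sm$scores, perm))
    null[b, ] <- tapply(r, chrom_f, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  }
  thr <- apply(null, 2L, quantile, probs = 1 - alpha, na.rm = TRUE,
               names = FALSE)
  chrom_stats <- data.frame(chrom = chroms,
                            observed_max = as.numeric(obs_max),
                            threshold = thr,
                            flagged = !is.na(obs_max) & obs_max > thr,
                            stringsAsFactors = FALSE)
  sig <- !is.na(obs_range) & obs_range > thr[match(chrom, chroms)]
  structure(list(observed = frequency_track(chrom, sm$markers$pos,
                                            obs_range,
                                            length(levels(groups))),
                 chrom_stats = chrom_stats,
                 significant = sm$markers$id[sig],
                 null = null,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "permutation_result")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result: ", x$n_perm, " permutations, alpha = ", x$alpha,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  chromosomes flagged: ",
      sum(x$chrom_stats$flagged), "/", nrow(x$chrom_stats),
      "; significant markers: ", length(x$significant), "\n", sep = "")
  invisible(x)
}
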