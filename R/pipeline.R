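#' Assemble a pipeline configuration
#'
#' Either `input` (paths to donor/SC/EP genotype files and a pairing table)
#' or `simulation` (a [sim_config()]) must be supplied. Threshold defaults
#' are the package-wide analysis defaults documented in their home
#' functions: 64 bp LD pruning, MAF > 0.10 for the PCA subset, marker QC at
#' 20\% and pair QC at 10\% unexpected genotypes, anchoring eligibility at
#' 20 calls / 10\% frequency, 200 permutations at alpha 0.05, and a 4\%
#' linkage threshold on the frequency track.
#'
#' @param input NULL, or list with `donor`, `sc`, `ep` (genotype file paths)
#'   and `pairing` (TSV with columns sc, ep).
#' @param simulation NULL, or a [sim_config()].
#' @param out_dir output directory (created if needed); NULL = no files
#'   written.
#' @param maf,ld_window_bp,marker_max_unexpected,pair_max_unexpected
#'   analysis thresholds (see Description).
#' @param anchor_min_calls,anchor_min_freq,n_perm,alpha,linkage_threshold
#'   analysis thresholds (see Description).
#' @param min_concordance,majority donor-consensus parameters.
#' @param pc1_split,pc2_split subpopulation PCA thresholds (see
#'   [pca_assign()]; recalibrate for real data).
#' @param seed integer seed governing the permutation test (and the
#'   simulation, unless its config carries its own seed).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, out_dir = NULL,
                            maf = 0.10, ld_window_bp = 64,
                            marker_max_unexpected = 0.20,
                            pair_max_unexpected = 0.10,
                            anchor_min_calls = 20, anchor_min_freq = 0.10,
                            n_perm = 200, alpha = 0.05,
                            linkage_threshold = 4,
                            min_concordance = 0.8, majority = 0.8,
                            pc1_split = 0, pc2_split = -20,
                            seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input or simulation must be given")
  stopifnot(maf >= 0, maf <= 0.5, ld_window_bp >= 0,
            marker_max_unexpected >= 0, marker_max_unexpected <= 1,
            pair_max_unexpected >= 0, pair_max_unexpected <= 1,
            anchor_min_calls >= 1, anchor_min_freq >= 0, anchor_min_freq <= 1,
            n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(input = input, simulation = simulation, out_dir = out_dir,
                 maf = maf, ld_window_bp = ld_window_bp,
                 marker_max_unexpected = marker_max_unexpected,
                 pair_max_unexpected = pair_max_unexpected,
                 anchor_min_calls = anchor_min_calls,
                 anchor_min_freq = anchor_min_freq,
                 n_perm = n_perm, alpha = alpha,
                 linkage_threshold = linkage_threshold,
                 min_concordance = min_concordance, majority = majority,
                 pc1_split = pc1_split, pc2_split = pc2_split,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  strip <- config[setdiff(names(config), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(strip, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a `simulation` block is
#' passed to [sim_config()] (its `targets` sub-block as a data.frame).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$targets))
      s$targets <- do.call(rbind, lapply(s$targets, as.data.frame))
    if (!is.null(s$groups) && !is.null(s$groups$sizes))
      s$groups$sizes <- as.integer(unlist(s$groups$sizes))
    y$simulation <- do.call(sim_config, s)
  }
  do.call(pipeline_config, y)
}

#' Run the full introgression-mapping pipeline
#'
#' Stages, in fixed order: load or simulate the genotype trios; build the
#' donor consensus; prune redundant markers (complete LD within the bp
#' window, computed on the combined SC+EP panel); classify every marker for
#' every pair; marker-level then pair-level unexpected-genotype QC; impute
#' fractional scores; genome-wide introgression frequency; Hudson Fst
#' between the full SC and EP panels; subpopulation assignment (truth groups
#' when simulated with groups, else PCA thresholds on the MAF-filtered EP
#' panel) and the permutation range test; LD anchoring of unanchored-contig
#' SNPs. Every discard count is logged via `message()`, and all tracks and
#' tables are written under `out_dir` when set, stamped with the config hash
#' and seed. Reruns with the same config and seed are bit-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param quiet suppress progress messages.
#' @return a `report_bundle` list: `consensus`, `tcm` (post-QC),
#'   `marker_qc`, `pair_qc`, `scores`, `frequency`, `fst`, `subpop`
#'   (tracks + range), `permutation`, `anchoring`, `class_counts`,
#'   `linkage_regions` (markers above the linkage threshold), `groups`,
#'   `config`, `config_hash`, `seed`, and `dataset` when simulated.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[introgmap] ", ...)
  hash <- config_hash(config)
  say("config ", hash, ", seed ", config$seed)

  ds <- NULL
  if (!is.null(config$simulation)) {
    say("stage simulate: ", config$simulation$n_pairs, " pairs")
    ds <- simulate_conversion(config$simulation)
    nz <- config$simulation$noise
    ds <- add_noise(ds, missing = nz$missing, het = nz$het,
                    unexpected = nz$unexpected, mode = nz$mode)
    donor <- ds$donor; sc <- ds$sc; ep <- ds$ep
    pairing <- ds$pairing
  } else {
    say("stage load")
    donor <- load_or_die(config$input$donor, "donor")
    sc <- load_or_die(config$input$sc, "sc")
    ep <- load_or_die(config$input$ep, "ep")
    pairing <- read.delim(config$input$pairing, stringsAsFactors = FALSE)
    common <- Reduce(intersect, list(donor$markers$id, sc$markers$id,
                                     ep$markers$id))
    if (!length(common)) stop("stage load: inputs share no markers")
    donor <- subset_gm(donor, markers = common)
    sc <- subset_gm(sc, markers = common)
    ep <- subset_gm(ep, markers = common)
  }

  say("stage consensus: ", length(donor$samples), " donor libraries")
  consensus <- consensus_donor(donor, config$min_concordance,
                               config$majority)
  if (nrow(consensus$dropped_libraries))
    say("  dropped libraries: ",
        paste(consensus$dropped_libraries$library, collapse = ", "))

  say("stage prune: LD window ", config$ld_window_bp, " bp")
  combined <- genotype_matrix(sc$markers, cbind(sc$calls, ep$calls))
  pruned <- prune_redundant_markers(combined, config$ld_window_bp)
  n_drop <- length(attr(pruned, "dropped"))
  say("  removed ", n_drop, " redundant markers")
  keep_ids <- pruned$markers$id
  sc <- subset_gm(sc, markers = keep_ids)
  ep <- subset_gm(ep, markers = keep_ids)

  say("stage call")
  tcm <- classify_all(sc, ep, consensus, pairing)
  counts <- call_class_counts(tcm)

  say("stage qc")
  mqc <- marker_qc(tcm, config$marker_max_unexpected)
  say("  markers discarded (>",
      100 * config$marker_max_unexpected, "% unexpected): ",
      length(mqc$removed))
  pqc <- pair_qc(mqc$tcm, config$pair_max_unexpected)
  say("  pairs discarded (>", 100 * config$pair_max_unexpected,
      "% unexpected): ", length(pqc$removed))
  tcm_qc <- pqc$tcm

  say("stage impute")
  sm <- impute_scores(tcm_qc)
  say("stage freq")
  freq <- introgression_frequency(sm)
  linkage <- freq[!is.na(freq$value) &
                    freq$value > config$linkage_threshold, , drop = FALSE]

  say("stage fst")
  fst <- hudson_fst(sc, ep)

  say("stage subpop")
  groups <- NULL
  if (!is.null(ds) && !all(is.na(pairing$group))) {
    groups <- setNames(pairing$group, pairing$sc)[tcm_qc$pairs$sc]
  } else {
    maf_ids <- filter_maf(genotype_matrix(sc$markers,
                                          cbind(sc$calls, ep$calls)),
                          config$maf)$markers$id
    say("  PCA on ", length(maf_ids), " markers with MAF > ",
        config$maf)
    assign <- pca_assign(subset_gm(ep, markers = maf_ids),
                         config$pc1_split, config$pc2_split)
    ep_of <- setNames(pairing$ep, pairing$sc)
    grp <- setNames(assign$assignment$group, assign$assignment$sample)
    groups <- grp[ep_of[tcm_qc$pairs$sc]]
    names(groups) <- tcm_qc$pairs$sc
  }
  subpop <- NULL; perm <- NULL
  if (length(unique(groups[!is.na(groups)])) >= 2L) {
    subpop <- subpop_frequencies(sm, groups)
    perm <- permutation_range_test(sm, groups, config$n_perm,
                                   config$alpha, config$seed)
    say("  chromosomes flagged: ", sum(perm$chrom_stats$flagged))
  } else {
    say("  <2 subpopulations; permutation test skipped")
  }

  say("stage anchor")
  anchoring <- NULL
  elig <- eligible_unanchored(tcm_qc, config$anchor_min_calls,
                              config$anchor_min_freq)
  say("  eligible unanchored SNPs: ", length(elig))
  if (length(elig))
    anchoring <- anchor_by_r2(tcm_qc, elig,
                              min_calls = config$anchor_min_calls)

  bundle <- structure(
    list(consensus = consensus, tcm = tcm_qc, marker_qc = mqc,
         pair_qc = pqc, scores = sm, frequency = freq, fst = fst,
         subpop = subpop, permutation = perm, anchoring = anchoring,
         class_counts = counts, linkage_regions = linkage,
         groups = groups, dataset = ds, config = config,
         config_hash = hash, seed = config$seed),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir, say)
  bundle
}

load_or_die <- function(path, what) {
  if (is.null(path)) stop("missing input path for ", what)
  read_genotype_table(path)
}

write_bundle <- function(bundle, dir, say) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(sprintf("# config_hash: %s", bundle$config_hash),
             sprintf("# seed: %d", bundle$seed))
  wt <- function(track, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    con <- file(path, "a")
    on.exit(close(con))
    write.table(data.frame(chrom = track$chrom, start0 = track$pos - 1,
                           end0 = track$pos, value = track$value),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  wt(bundle$frequency, "introgression_frequency.bed.tsv")
  wt(bundle$fst, "fst.bed.tsv")
  if (!is.null(bundle$subpop)) {
    wt(bundle$subpop$range, "subpop_range.bed.tsv")
    for (g in names(bundle$subpop$tracks))
      wt(bundle$subpop$tracks[[g]], sprintf("frequency_%s.bed.tsv", g))
  }
  write_scores(bundle$scores, file.path(dir, "introgression_scores.tsv"))
  if (!is.null(bundle$permutation))
    write.table(bundle$permutation$chrom_stats,
                file.path(dir, "permutation_thresholds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$anchoring))
    write_placements(bundle$anchoring, file.path(dir, "anchoring.tsv"))
  qc <- data.frame(class = names(bundle$class_counts),
                   count = as.integer(bundle$class_counts))
  write.table(qc, file.path(dir, "qc_class_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, seed = bundle$seed,
         markers_removed_qc = length(bundle$marker_qc$removed),
         pairs_removed_qc = length(bundle$pair_qc$removed)),
    file.path(dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  say("wrote outputs to ", dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (config ", x$config_hash, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  pairs retained: ", nrow(x$tcm$pairs), "; markers retained: ",
      nrow(x$tcm$markers), "\n", sep = "")
  cat("  markers above linkage threshold: ", nrow(x$linkage_regions),
      "\n", sep = "")
  invisible(x)
}
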