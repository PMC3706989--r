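small_cfg <- function(...) {
  sim_config(n_pairs = 12, markers_per_chrom = 40, n_chrom = 3,
             chrom_length = 1.6, noise = list(missing = 0, het = 0,
                                              unexpected = 0),
             n_donor_libs = 4, donor_lib_error = 0, seed = 77, ...)
}

test_that("simulated trios satisfy the ground-truth invariants", {
  ds <- simulate_conversion(small_cfg())
  mk <- ds$sc$markers
  expect_identical(ds$ep$markers, mk)
  expect_identical(ds$donor$markers, mk)
  # SC equals donor allele inside tracts and EP allele outside (pre-noise)
  donor_allele <- mk$ref
  ep_first <- substr(ds$ep$calls[, ds$pairing$ep], 1, 1)
  sc_first <- substr(ds$sc$calls[, ds$pairing$sc], 1, 1)
  st <- ds$truth$states
  expect_true(all(sc_first[st == 1L] == donor_allele[row(st)[st == 1L]]))
  expect_true(all(sc_first[st == 0L] == ep_first[st == 0L]))
  # truth tracts are disjoint per chromosome and line
  tr <- ds$truth$tracts
  by_cl <- split(tr, paste(tr$line, tr$chrom))
  ok <- vapply(by_cl, function(x) {
    x <- x[order(x$start), ]
    nrow(x) < 2 || all(x$start[-1] > x$end[-nrow(x)])
  }, logical(1))
  expect_true(all(ok))
  # tracts agree with marker states
  expect_true(all(st %in% c(0L, 1L)))
  # determinism given the config seed
  ds2 <- simulate_conversion(small_cfg())
  expect_identical(ds2$sc$calls, ds$sc$calls)
  expect_identical(ds2$truth$states, ds$truth$states)
})

test_that("group-specific targets are selected only in their subpopulation", {
  # put the targets exactly at marker genetic positions so the truth state
  # at the target marker is deterministic under selection
  ref_map <- genetic_map(n_chrom = 2, chrom_length = 1.6,
                         markers_per_chrom = 30)
  g1 <- ref_map$markers$gpos[ref_map$markers$chrom == "Chr01"][15]
  g2 <- ref_map$markers$gpos[ref_map$markers$chrom == "Chr02"][8]
  cfg <- sim_config(n_pairs = 12, markers_per_chrom = 30, n_chrom = 2,
                    noise = list(missing = 0, het = 0, unexpected = 0),
                    groups = list(sizes = c(6, 6), labels = c("C", "D")),
                    targets = data.frame(chrom = c("Chr01", "Chr02"),
                                         gpos = c(g1, g2),
                                         group = c(NA, "D")),
                    seed = 3)
  ds <- simulate_conversion(cfg)
  map <- ds$map
  t1 <- which(map$markers$chrom == "Chr01" & map$markers$gpos == g1)
  t2 <- which(map$markers$chrom == "Chr02" & map$markers$gpos == g2)
  st <- ds$truth$states
  grp <- ds$pairing$group
  expect_true(all(st[t1, ] == 1L))            # global target: every line
  expect_true(all(st[t2, grp == "D"] == 1L))  # group target: D lines only
  expect_lt(mean(st[t2, grp == "C"]), 1)      # not enforced in C
})

test_that("add_noise with zero rates is the identity", {
  ds <- simulate_conversion(small_cfg())
  ds2 <- add_noise(ds, missing = 0, het = 0, unexpected = 0)
  expect_identical(ds2$sc$calls, ds$sc$calls)
  expect_identical(ds2$ep$calls, ds$ep$calls)
  expect_identical(ds2$donor$calls, ds$donor$calls)
})

test_that("noise rates are realized at the configured magnitudes", {
  cfg <- sim_config(n_pairs = 20, markers_per_chrom = 150, n_chrom = 4,
                    noise = list(missing = 0, het = 0, unexpected = 0),
                    n_donor_libs = 4, donor_lib_error = 0, seed = 19)
  ds <- simulate_conversion(cfg)
  nds <- add_noise(ds, missing = 0.66, het = 0.01, seed = 101)
  expect_equal(mean(nds$sc$calls == "NN"), 0.66, tolerance = 0.02)
  het <- introgmap:::gt_is_het(nds$sc$calls)
  # het cells drawn before missing overwrite ~ 0.01 * (1 - 0.66)
  expect_equal(mean(het), 0.01 * 0.34, tolerance = 0.25)
})

test_that("a scattered unexpected rate of 15% trips the 10% pair filter", {
  cfg <- sim_config(n_pairs = 8, markers_per_chrom = 120, n_chrom = 4,
                    noise = list(missing = 0, het = 0, unexpected = 0),
                    n_donor_libs = 4, donor_lib_error = 0, seed = 23)
  ds <- simulate_conversion(cfg)
  rates <- c(0.15, rep(0, 7))
  nds <- add_noise(ds, unexpected = rates, seed = 29)
  cons <- consensus_donor(nds$donor)
  tcm <- classify_all(nds$sc, nds$ep, cons, nds$pairing)
  frac <- introgmap:::unexpected_fraction(tcm$calls, 2L)
  expect_equal(unname(frac[1]), 0.15, tolerance = 0.2)
  expect_true(all(frac[-1] == 0))
  pq <- pair_qc(tcm, max_unexpected = 0.10)
  expect_equal(pq$removed, "SC0001")
})

test_that("segmental and pair_swap modes produce their signatures", {
  cfg <- sim_config(n_pairs = 6, markers_per_chrom = 200, n_chrom = 2,
                    noise = list(missing = 0, het = 0, unexpected = 0),
                    n_donor_libs = 3, donor_lib_error = 0, seed = 37)
  ds <- simulate_conversion(cfg)
  seg <- add_noise(ds, unexpected = c(0.2, rep(0, 5)), mode = "segmental",
                   seed = 41)
  changed <- which(seg$sc$calls[, 1] != ds$sc$calls[, 1])
  expect_gt(length(changed), 10)
  # one contiguous block in marker index space (among polymorphic cells)
  expect_lt(diff(range(changed)), 0.35 * nrow(ds$sc$markers))
  # pair swap rewires the pairing, not the genotypes
  sw <- add_noise(ds, unexpected = c(0.5, 0.5, 0, 0, 0, 0),
                  mode = "pair_swap", seed = 43)
  expect_identical(sw$sc$calls, ds$sc$calls)
  expect_equal(sw$pairing$ep[1:2], ds$pairing$ep[2:1])
})

test_that("relocated contig SNPs keep their calls and record their origin", {
  ds <- simulate_conversion(small_cfg())
  out <- relocate_to_contigs(ds, n_contigs = 5, snps_per_contig = 2,
                             seed = 47)
  tr <- out$truth
  expect_equal(nrow(tr), 10)
  expect_true(all(is_unanchored_chrom(
    out$ds$sc$markers$chrom[match(tr$snp_id, out$ds$sc$markers$id)])))
  # calls for a relocated SNP are untouched
  for (id in tr$snp_id[1:3]) {
    expect_identical(out$ds$sc$calls[id, ], ds$sc$calls[id, ])
  }
  # truth states stay aligned with the reordered marker table
  expect_identical(rownames(out$ds$truth$states), out$ds$sc$markers$id)
  st_orig <- ds$truth$states[out$ds$sc$markers$id, ]
  expect_identical(unname(out$ds$truth$states), unname(st_orig))
})
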