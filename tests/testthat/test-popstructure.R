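test_that("PCA threshold rules assign the three subpopulations", {
  expect_equal(assign_from_pcs(10, -25), "GK")
  expect_equal(assign_from_pcs(5, 0), "C")
  expect_equal(assign_from_pcs(-5, 0), "D")
  expect_equal(assign_from_pcs(c(1, -1, 0), c(0, 0, -30)),
               c("C", "D", "GK"))
})

test_that("pca_assign separates simulated subpopulations and is stable for duplicates", {
  set.seed(21)
  n_per <- 15; m <- 400
  p1 <- runif(m, 0.05, 0.95)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-0.4, 0.4), m, TRUE)))
  draw <- function(p, n) {
    a <- matrix(rbinom(m * n, 1, p), m, n)
    ifelse(a == 1, "GG", "AA")
  }
  calls <- cbind(draw(p1, n_per), draw(p2, n_per))
  # two identical samples
  calls <- cbind(calls, calls[, 1], calls[, 1])
  colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  gm <- make_gm(calls)
  res <- pca_assign(gm, pc1_split = 0, pc2_split = -1e9)
  a <- res$assignment
  # the two true populations split cleanly along canonicalized PC1
  g1 <- a$group[1:n_per]
  g2 <- a$group[(n_per + 1):(2 * n_per)]
  expect_true(length(unique(g1)) == 1 && length(unique(g2)) == 1)
  expect_false(g1[1] == g2[1])
  # identical samples get identical coordinates and the same group
  last2 <- a[a$sample %in% c("s31", "s32"), ]
  expect_equal(last2$PC1, rep(a$PC1[1], 2), tolerance = 1e-8)
  expect_equal(last2$group, rep(a$group[1], 2))
  expect_error(pca_assign(subset_gm(gm, samples = 1:2)), "3 samples")
})

test_that("hudson Fst matches its closed form and limiting values", {
  f <- introgmap:::fst_hudson_counts
  # no differentiation, large n -> ~0; fixed difference -> 1
  expect_lt(abs(f(0.5, 1e6, 0.5, 1e6)), 1e-5)
  expect_equal(f(1, 20, 0, 20), 1)
  # counts (n1=20, 12 alt; n2=20, 4 alt): transcribe the formula directly
  p1 <- 12 / 20; p2 <- 4 / 20
  want <- ((p1 - p2)^2 - p1 * (1 - p1) / 19 - p2 * (1 - p2) / 19) /
    (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(f(p1, 20, p2, 20), want, tolerance = 1e-15)
})

test_that("hudson_fst on genotype panels counts haploid alleles and handles NA", {
  # panel A: 6 samples 12 alleles, 8 alt; panel B: 5 samples 10 alleles, 1 alt
  a_calls <- matrix(c("GG", "GG", "GG", "AG", "AG", "AA"), 1, 6)
  b_calls <- matrix(c("AG", "AA", "AA", "AA", "NN"), 1, 5)
  colnames(a_calls) <- paste0("a", 1:6)
  colnames(b_calls) <- paste0("b", 1:5)
  fst <- hudson_fst(make_gm(a_calls), make_gm(b_calls))
  p1 <- 8 / 12; n1 <- 12; p2 <- 1 / 8; n2 <- 8
  want <- ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)) /
    (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(fst$value, want)
  # monomorphic in both -> undefined
  mono <- hudson_fst(make_gm(matrix("AA", 1, 3, dimnames = list(NULL, paste0("a", 1:3)))),
                     make_gm(matrix("AA", 1, 3, dimnames = list(NULL, paste0("b", 1:3)))))
  expect_true(is.na(mono$value))
})

test_that("hudson_fst is near zero for panels drawn from one population", {
  set.seed(5)
  m <- 12000; n <- 40
  p <- runif(m, 0.05, 0.95)
  draw <- function() {
    a <- matrix(rbinom(m * n, 2, p), m, n)
    out <- matrix("AG", m, n)
    out[a == 0] <- "AA"; out[a == 2] <- "GG"
    colnames(out) <- paste0("s", sample.int(1e9, n))
    out
  }
  fst <- hudson_fst(make_gm(draw()), make_gm(draw()))
  expect_lt(abs(mean(fst$value, na.rm = TRUE)), 0.002)
})

test_that("subpopulation frequencies, their range, and label-permutation conservation", {
  sm <- make_sm(cbind(c(1, 0), c(1, 0), c(0, 0), c(0, 0), c(1, 1), c(0, 1)))
  groups <- c("C", "C", "D", "D", "GK", "GK")
  out <- subpop_frequencies(sm, groups)
  expect_equal(out$tracks$C$value, c(100, 0))
  expect_equal(out$tracks$GK$value, c(50, 100))
  expect_equal(out$range$value, c(100, 100))
  # equal scores across groups -> range 0
  smf <- make_sm(matrix(0.4, 2, 6))
  expect_equal(subpop_frequencies(smf, groups)$range$value, c(0, 0))
  # (90, 3, 3) -> range 87
  expect_equal(subpop_frequencies(
    make_sm(matrix(c(0.9, 0.03, 0.03), 1, 3)),
    c("C", "D", "GK"))$range$value, 87)
  # permuting labels preserves the pooled frequency track
  set.seed(2)
  perm <- sample(groups)
  pooled <- introgression_frequency(sm)$value
  out_p <- subpop_frequencies(sm, perm)
  sizes <- table(perm)[names(out_p$tracks)]
  mixed <- Reduce(`+`, Map(function(tr, w) tr$value * w,
                           out_p$tracks, as.numeric(sizes))) / sum(sizes)
  expect_equal(mixed, pooled)
  expect_error(subpop_frequencies(sm, factor(groups, levels = c(unique(groups), "X"))),
               "empty")
})

test_that("permutation range test is deterministic and detects a strong group effect", {
  set.seed(31)
  n_per <- 45
  groups <- rep(c("C", "D", "GK"), each = n_per)
  m <- 60
  scores <- matrix(rbinom(m * n_per * 3, 1, 0.03), m, n_per * 3)
  # marker 10 on Chr01: ~90% in group C only
  scores[10, 1:n_per] <- rbinom(n_per, 1, 0.9)
  chrom <- rep(c("Chr01", "Chr02"), each = m / 2)
  sm <- make_sm(scores, chrom = chrom)
  r1 <- permutation_range_test(sm, groups, n_perm = 100, seed = 42)
  r2 <- permutation_range_test(sm, groups, n_perm = 100, seed = 42)
  expect_identical(r1, r2)
  expect_true("m10" %in% r1$significant)
  expect_true(r1$chrom_stats$flagged[r1$chrom_stats$chrom == "Chr01"])
  expect_warning(permutation_range_test(sm, groups, n_perm = 10, seed = 1),
                 "unstable")
})

test_that("permutation null distribution is invariant to marker order", {
  set.seed(8)
  scores <- matrix(runif(40 * 30), 40, 30)
  groups <- rep(c("C", "D", "GK"), each = 10)
  sm <- make_sm(scores)
  shuf <- sample(40)
  sm_shuf <- make_sm(scores[shuf, ], pos = sort(seq_len(40)[shuf]) * 1000)
  r_a <- permutation_range_test(sm, groups, n_perm = 50, seed = 3)
  r_b <- permutation_range_test(sm_shuf, groups, n_perm = 50, seed = 3)
  expect_equal(r_a$null, r_b$null)
  expect_equal(r_a$chrom_stats$threshold, r_b$chrom_stats$threshold)
})
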