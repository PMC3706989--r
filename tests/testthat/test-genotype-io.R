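test_that("hapmap round-trip preserves calls and coordinates exactly", {
  gm <- make_gm(matrix(c("AA", "AG", "NN",
                         "GG", "AA", "AA"), nrow = 3,
                       dimnames = list(NULL, c("s1", "s2"))),
                pos = c(100, 250, 9000))
  f <- write_tmp_hapmap(gm)
  back <- read_genotype_table(f, format = "hapmap")
  expect_identical(back$calls, gm$calls)
  expect_identical(back$markers, gm$markers)
  expect_identical(back$samples, gm$samples)
})

test_that("vcf round-trip preserves calls and coordinates exactly", {
  gm <- make_gm(matrix(c("AA", "AG", "NN", "GG",
                         "GG", "AA", "AA", "AG"), nrow = 4,
                       dimnames = list(NULL, c("s1", "s2"))),
                pos = c(5, 70, 800, 9000))
  f <- tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_genotype_table(f)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$markers, gm$markers)
})

test_that("multi-allelic sites are dropped with a logged count", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "Chr01\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
    "Chr01\t200\tv2\tA\tG,T\t.\t.\t.\tGT\t0/1\t2/2",
    "Chr01\t300\tv3\tC\tT\t.\t.\t.\tGT\t0|1\t./.",
    "Chr01\t400\tv4\tG\tA\t.\t.\t.\tGT\t1/1\t0/0",
    "Chr01\t500\tv5\tT\tC\t.\t.\t.\tGT\t0/0\t0/0"),
    f)
  expect_message(gm <- read_genotype_table(f), "dropped 1")
  expect_equal(nrow(gm$markers), 4)
  expect_false("v2" %in% gm$markers$id)
  # phased and unphased GT read identically; ./. becomes NN
  expect_equal(unname(gm$calls["v3", ]), c("CT", "NN"))
})

test_that("parse errors name the offending line; duplicates are errors", {
  f <- tempfile()
  writeLines(character(), f)
  expect_error(read_genotype_table(f, format = "hapmap"), "empty")

  f2 <- tempfile()
  writeLines(c("rs#\talleles\tchrom\tpos\ts1\ts2",
               "m1\tA/G\tChr01\t100\tAA\tGG",
               "m2\tA/G\tChr01\t200\tAA"), f2)
  expect_error(read_genotype_table(f2, format = "hapmap"), "line 3")

  f3 <- tempfile()
  writeLines(c("rs#\talleles\tchrom\tpos\ts1\ts1",
               "m1\tA/G\tChr01\t100\tAA\tGG"), f3)
  expect_error(read_genotype_table(f3, format = "hapmap"),
               "duplicated sample")
})

test_that("markers are sorted with unanchored contigs after chromosomes", {
  gm <- genotype_matrix(
    data.frame(id = c("a", "b", "c", "d"),
               chrom = c("contig_07", "Chr02", "Chr01", "Chr01"),
               pos = c(10, 5, 900, 20),
               ref = "A", alt = "G"),
    matrix("AA", 4, 1, dimnames = list(NULL, "s1")))
  expect_equal(gm$markers$id, c("d", "c", "b", "a"))
})

test_that("donor consensus takes homozygous majority and drops outlier libraries", {
  # 25 unanimous libraries
  gm <- make_gm(matrix("AA", 3, 25,
                       dimnames = list(NULL, paste0("L", 1:25))))
  cons <- consensus_donor(gm)
  expect_equal(cons$n_libraries_used, 25)
  expect_equal(unname(cons$calls), rep("AA", 3))

  # 28 libraries, 3 of them discordant with the rest at most markers
  good <- matrix(c("AA", "GG", "CC", "TT"), 40, 25)
  bad <- matrix(c("GG", "AA", "TT", "CC"), 40, 3)
  calls <- cbind(good, bad)
  colnames(calls) <- paste0("L", 1:28)
  gm2 <- make_gm(calls)
  cons2 <- consensus_donor(gm2, min_concordance = 0.8)
  expect_equal(nrow(cons2$dropped_libraries), 3)
  expect_setequal(cons2$dropped_libraries$library, paste0("L", 26:28))
  expect_equal(cons2$n_libraries_used, 25)

  # tie 2 AA vs 2 GG -> missing; het majority -> missing
  gm3 <- make_gm(matrix(c("AA", "AA", "GG", "GG",
                          "AG", "AG", "AG", "AA"), nrow = 2, byrow = TRUE,
                        dimnames = list(NULL, paste0("L", 1:4))))
  cons3 <- consensus_donor(gm3, min_concordance = 0, majority = 0.5)
  expect_equal(unname(cons3$calls), c("NN", "NN"))

  expect_error(consensus_donor(subset_gm(gm2, samples = paste0("L", 26:28)),
                               min_concordance = 2),
               "all donor libraries dropped")
})

test_that("donor consensus is invariant to library order", {
  set.seed(42)
  calls <- matrix(sample(c("AA", "GG", "AG", "NN"), 200, replace = TRUE),
                  20, 10, dimnames = list(NULL, paste0("L", 1:10)))
  gm <- make_gm(calls)
  perm <- sample(10)
  gm_p <- subset_gm(gm, samples = paste0("L", perm))
  expect_identical(consensus_donor(gm, min_concordance = 0)$calls,
                   consensus_donor(gm_p, min_concordance = 0)$calls)
})

test_that("MAF filter is strict and drops all-missing markers", {
  calls <- rbind(
    c("AA", "AA", "GG", "GG"),         # 50/50 -> kept
    c("AA", "AA", "AA", "AA"),         # monomorphic -> dropped
    c("NN", "NN", "NN", "NN"),         # all missing -> dropped
    c("AA", "AA", "AA", "AA"))         # monomorphic -> dropped
  # exactly 10% minor allele: 1 alt allele in 10 -> dropped at min_maf = 0.10
  calls10 <- matrix("AA", 1, 5)
  calls10[1, 1] <- "AG"
  gm10 <- make_gm(calls10)
  expect_equal(nrow(filter_maf(gm10, 0.10)$markers), 0)
  expect_equal(nrow(filter_maf(gm10, 0.09)$markers), 1)

  colnames(calls) <- paste0("s", 1:4)
  gm <- make_gm(calls)
  expect_message(out <- filter_maf(gm, 0.10), "all-missing")
  expect_equal(out$markers$id, "m1")
  expect_setequal(attr(out, "dropped"), c("m2", "m3", "m4"))
})

test_that("redundant-marker pruning removes only complete-LD markers within the window", {
  s <- c("AA", "AA", "GG", "GG", "AA")
  dup <- rbind(s, s)
  colnames(dup) <- paste0("s", 1:5)

  # identical, 30 bp apart -> second removed
  gm <- make_gm(dup, pos = c(100, 130))
  expect_message(out <- prune_redundant_markers(gm), "removed 1")
  expect_equal(out$markers$id, "m1")

  # identical, exactly 64 bp apart -> both kept (strict <)
  gm64 <- make_gm(dup, pos = c(100, 164))
  expect_equal(nrow(prune_redundant_markers(gm64)$markers), 2)

  # one discordant sample -> both kept
  d2 <- dup; d2[2, 5] <- "GG"
  gmd <- make_gm(d2, pos = c(100, 130))
  expect_equal(nrow(prune_redundant_markers(gmd)$markers), 2)

  # identical but constant on shared samples -> not complete LD -> kept
  mono <- rbind(rep("AA", 5), rep("AA", 5))
  colnames(mono) <- paste0("s", 1:5)
  gmm <- make_gm(mono, pos = c(100, 130))
  expect_equal(nrow(prune_redundant_markers(gmm)$markers), 2)

  # a redundant run keeps only its leftmost member, and pruning is idempotent
  run <- do.call(rbind, replicate(4, s, simplify = FALSE))
  colnames(run) <- paste0("s", 1:5)
  gmr <- make_gm(run, pos = c(100, 120, 140, 260))
  out1 <- prune_redundant_markers(gmr)
  expect_equal(out1$markers$id, c("m1", "m4"))
  out2 <- prune_redundant_markers(out1)
  expect_identical(out2$markers, out1$markers)
})
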