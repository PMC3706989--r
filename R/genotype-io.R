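#' Read a genotype matrix from a HapMap-style TSV or a VCF
#'
#' Two dialects are accepted. The HapMap-style table has header columns
#' `rs#`, `alleles`, `chrom`, `pos`, followed by one column per sample with
#' two-letter genotypes (`AA`, `AG`, `NN` = missing). VCF v4.x is read
#' through \pkg{vcfR}; only the GT field is consumed and phased/unphased
#' genotypes are treated identically. Multi-allelic sites are dropped with a
#' message stating the count.
#'
#' @param path path to the genotype file.
#' @param format `"auto"` (default; by extension), `"hapmap"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, format = c("auto", "hapmap", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "hapmap"
  }
  if (format == "hapmap") read_hapmap(path) else read_vcf(path)
}

read_hapmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L)
    stop("parse error in ", path, ": empty file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("rs#", "alleles", "chrom", "pos")
  if (length(header) < 5L || !all(need == head(header, 4L)))
    stop("parse error in ", path, " line 1: expected header columns ",
         paste(need, collapse = ", "), " followed by sample columns")
  samples <- header[-(1:4)]
  if (anyDuplicated(samples))
    stop("duplicated sample id in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  ncol_exp <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != ncol_exp)) {
    bad <- which(nfield != ncol_exp)[1L]
    stop("parse error in ", path, " line ", bad + 1L, ": expected ",
         ncol_exp, " fields, found ", nfield[bad])
  }
  tab <- matrix(unlist(body), ncol = ncol_exp, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(tab[, 4L]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("parse error in ", path, " line ", bad + 1L,
         ": non-numeric position '", tab[bad, 4L], "'")
  }
  alle <- strsplit(tab[, 2L], "/", fixed = TRUE)
  nall <- lengths(alle)
  multi <- nall > 2L
  if (any(multi))
    message("read_hapmap: dropped ", sum(multi), " multi-allelic site(s)")
  keep <- !multi
  markers <- data.frame(
    id = tab[keep, 1L],
    chrom = tab[keep, 3L],
    pos = pos[keep],
    ref = vapply(alle[keep], `[`, "", 1L),
    alt = vapply(alle[keep], function(a) if (length(a) > 1L) a[2L] else NA_character_, ""),
    stringsAsFactors = FALSE)
  calls <- tab[keep, -(1:4), drop = FALSE]
  colnames(calls) <- samples
  genotype_matrix(markers, calls)
}

read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("parse error in ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("parse error in ", path, ": no variant records")
  samples <- colnames(v@gt)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  multi <- grepl(",", alt, fixed = TRUE) |
    nchar(fix[, "REF"]) > 1L | (alt != "." & nchar(alt) > 1L)
  if (any(multi))
    message("read_vcf: dropped ", sum(multi),
            " multi-allelic or non-SNP site(s)")
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(keep) + sum(multi),
                                     dimnames = list(NULL, samples))
  gt <- gt[keep, , drop = FALSE]
  ref <- fix[keep, "REF"]
  altk <- alt[keep]
  # GT "0/0","0|1","./." -> two-letter genotype strings
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a2[nchar(gt) == 1L & !is.na(gt)] <- a1[nchar(gt) == 1L & !is.na(gt)]
  refm <- matrix(ref, nrow = length(keep), ncol = length(samples))
  altm <- matrix(altk, nrow = length(keep), ncol = length(samples))
  dec <- function(a) ifelse(is.na(a) | a == ".", "N",
                            ifelse(a == "0", refm, altm))
  calls <- matrix(paste0(dec(a1), dec(a2)),
                  nrow = length(keep), ncol = length(samples),
                  dimnames = list(NULL, samples))
  calls[is.na(gt)] <- GT_MISSING
  id <- fix[keep, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[keep, "CHROM"][noid], "_", fix[keep, "POS"][noid])
  markers <- data.frame(id = id,
                        chrom = fix[keep, "CHROM"],
                        pos = as.numeric(fix[keep, "POS"]),
                        ref = ref,
                        alt = ifelse(altk == ".", NA_character_, altk),
                        stringsAsFactors = FALSE)
  genotype_matrix(markers, calls)
}

#' Write a genotype matrix as a HapMap-style TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  alleles <- ifelse(is.na(gm$markers$alt), gm$markers$ref,
                    paste0(gm$markers$ref, "/", gm$markers$alt))
  tab <- cbind(gm$markers$id, alleles, gm$markers$chrom,
               format(gm$markers$pos, scientific = FALSE, trim = TRUE),
               gm$calls)
  colnames(tab) <- c("rs#", "alleles", "chrom", "pos", gm$samples)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits biallelic sites with a GT field only. Genotype calls whose alleles
#' are not the site's ref/alt (possible after noise injection) are written as
#' missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  ref <- gm$markers$ref
  alt <- ifelse(is.na(gm$markers$alt), ".", gm$markers$alt)
  a1 <- substr(gm$calls, 1L, 1L)
  a2 <- substr(gm$calls, 2L, 2L)
  refm <- matrix(ref, nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  altm <- matrix(alt, nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  code <- function(a) ifelse(a == refm, "0", ifelse(a == altm, "1", "."))
  gtm <- matrix(paste0(code(a1), "/", code(a2)),
                nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  gtm[gt_is_missing(gm$calls) | grepl(".", gtm, fixed = TRUE)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  body <- cbind(gm$markers$chrom,
                format(gm$markers$pos, scientific = FALSE, trim = TRUE),
                gm$markers$id, ref, alt, ".", ".", ".", "GT", gtm)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
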