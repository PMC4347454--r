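#' Construct a genotype table
#'
#' Holds additive minor-allele genotype calls (0 = no minor allele, 1 = one,
#' 2 = two, `NA` = missing call) for ordered subjects and SNPs, together
#' with per-SNP metadata (chromosome, position, minor/major allele labels).
#'
#' @param calls subjects-by-SNPs matrix with values in `{0, 1, 2, NA}`.
#' @param snp_info data frame with columns `id`, `chr`, `pos`, `minor`,
#'   `major` (defaults are generated when absent).
#' @param subjects character subject IDs.
#' @return a `genotype_table`.
#' @export
genotype_table <- function(calls, snp_info = NULL, subjects = NULL) {
  calls <- as.matrix(calls)
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  assert_that(all(ok), "genotype calls must be 0, 1, 2 or NA")
  if (is.null(subjects)) {
    subjects <- rownames(calls)
    if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  if (is.null(snp_info)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("rs%06d", seq_len(ncol(calls)))
    snp_info <- data.frame(id = ids, chr = 1L,
                           pos = seq_len(ncol(calls)) * 1000L,
                           minor = "A", major = "G",
                           stringsAsFactors = FALSE)
  }
  assert_that(nrow(snp_info) == ncol(calls),
              "snp_info rows must match the number of SNP columns")
  dimnames(calls) <- list(subjects, snp_info$id)
  structure(list(calls = calls, subjects = subjects, snp_info = snp_info),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d subjects x %d SNPs, %.2f%% missing>\n",
              length(x$subjects), nrow(x$snp_info),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

# Subset a genotype table by subject/SNP index, keeping metadata aligned.
gt_subset <- function(gt, subjects = NULL, snps = NULL) {
  if (is.null(subjects)) subjects <- seq_along(gt$subjects)
  if (is.null(snps)) snps <- seq_len(nrow(gt$snp_info))
  genotype_table(gt$calls[subjects, snps, drop = FALSE],
                 snp_info = gt$snp_info[snps, , drop = FALSE],
                 subjects = gt$subjects[subjects])
}

#' Minor allele frequencies of a genotype table
#'
#' Per-SNP frequency of the counted (minor) allele over non-missing calls.
#'
#' @param gt a [genotype_table()].
#' @return numeric vector, one value per SNP.
#' @export
genotype_maf <- function(gt) {
  colMeans(gt$calls, na.rm = TRUE) / 2
}

#' Convert genotype calls to a centered dosage modality matrix
#'
#' @param gt a [genotype_table()] without missing calls.
#' @param center subtract per-SNP means (default TRUE).
#' @return a [modality_matrix()] tagged `"snp"`.
#' @export
genotype_to_modality <- function(gt, center = TRUE) {
  assert_that(!anyNA(gt$calls), "impute or remove missing calls first")
  x <- gt$calls * 1.0
  if (center) x <- sweep(x, 2L, colMeans(x))
  modality_matrix(x, subjects = gt$subjects, variables = gt$snp_info$id,
                  modality = "snp")
}

#' Read a delimited dosage table
#'
#' Tab-separated text with a header row of SNP IDs and a first column of
#' subject IDs; calls coded 0/1/2 with a configurable missing marker.
#'
#' @param path file path.
#' @param missing_marker values treated as missing (default `NA` and -9).
#' @return a [genotype_table()].
#' @export
read_dosage <- function(path, missing_marker = c("NA", "-9")) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  row.names = 1L, na.strings = missing_marker)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  num_mark <- suppressWarnings(as.numeric(missing_marker))
  num_mark <- num_mark[!is.na(num_mark)]
  if (length(num_mark)) m[m %in% num_mark] <- NA
  genotype_table(m, subjects = rownames(d))
}

#' Write a genotype table as a delimited dosage file
#'
#' @param gt a [genotype_table()].
#' @param path output file path; missing calls written as `NA`.
#' @export
write_dosage <- function(gt, path) {
  d <- data.frame(id = gt$subjects, as.data.frame(gt$calls),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype table as a PLINK bed/bim/fam trio
#'
#' SNP-major bed layout with the counted (minor) allele as A1; missing
#' calls stored with the dedicated missing bit pattern.
#'
#' @param gt a [genotype_table()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @export
write_plink <- function(gt, prefix) {
  n <- length(gt$subjects)
  si <- gt$snp_info
  fam <- data.frame(fid = gt$subjects, iid = gt$subjects, pid = 0L, mid = 0L,
                    sex = 0L, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = si$chr, id = si$id, cm = 0L, pos = si$pos,
                    a1 = si$minor, a2 = si$major)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # 2-bit codes (A1 dosage): 0 copies -> 11, 1 -> 10, 2 -> 00, missing -> 01
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(nrow(si))) {
    g <- gt$calls[, j]
    two_bit <- ifelse(is.na(g), 1L, code[as.character(g)])
    two_bit <- c(two_bit, rep(0L, bytes_per_snp * 4L - n))
    b <- two_bit[c(TRUE, FALSE, FALSE, FALSE)] +
      two_bit[c(FALSE, TRUE, FALSE, FALSE)] * 4L +
      two_bit[c(FALSE, FALSE, TRUE, FALSE)] * 16L +
      two_bit[c(FALSE, FALSE, FALSE, TRUE)] * 64L
    writeBin(as.raw(b), con)
  }
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam trio
#'
#' Reads SNP-major bed files; genotypes are returned as counts of the A1
#' allele of the bim file (normalized so the counted allele is the minor
#' one: SNPs whose A1 frequency exceeds 0.5 are flipped and their allele
#' labels swapped).
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return a [genotype_table()].
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * p)
  assert_that(identical(raw[1:2], as.raw(c(0x6c, 0x1b))),
              "not a PLINK bed file")
  assert_that(raw[3] == as.raw(0x01), "only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  # dosage lookup by 2-bit code: 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0
  dos <- c(2, NA, 1, 0)
  calls <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    b <- body[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)]
    two_bit <- c(rbind(b %% 4L, (b %/% 4L) %% 4L,
                       (b %/% 16L) %% 4L, (b %/% 64L) %% 4L))
    calls[, j] <- dos[two_bit[seq_len(n)] + 1L]
  }
  snp_info <- data.frame(id = bim$V2, chr = bim$V1, pos = bim$V4,
                         minor = bim$V5, major = bim$V6,
                         stringsAsFactors = FALSE)
  # normalize to minor-allele counts
  freq <- colMeans(calls, na.rm = TRUE) / 2
  flip <- which(freq > 0.5)
  if (length(flip)) {
    calls[, flip] <- 2 - calls[, flip]
    tmp <- snp_info$minor[flip]
    snp_info$minor[flip] <- snp_info$major[flip]
    snp_info$major[flip] <- tmp
  }
  genotype_table(calls, snp_info = snp_info, subjects = fam$V2)
}
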