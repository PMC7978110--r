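#' Write a genotype panel as a PLINK bed/bim/fam triple
#'
#' SNP-major bed with the magic bytes `0x6c 0x1b 0x01`. Genotypes are
#' stored as counts of the bim A1 allele: two-bit codes 00 = two copies,
#' 10 = one copy, 11 = zero copies, 01 = missing, packed four individuals
#' per byte, least-significant bits first, each SNP padded to whole bytes.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  n <- nrow(g); m <- ncol(g)
  fam <- data.frame(fid = panel$sample_ids, iid = panel$sample_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chr = panel$chromosomes, id = panel$snp_ids, cm = 0L,
                    bp = panel$positions, a1 = "A", a2 = "C")
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # 2-bit code by allele count: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 2] <- 0L
  npad <- ceiling(n / 4) * 4
  if (npad > n) code <- rbind(code, matrix(0L, npad - n, m))
  bytes <- code[seq(1, npad, 4), , drop = FALSE] +
    4L * code[seq(2, npad, 4), , drop = FALSE] +
    16L * code[seq(3, npad, 4), , drop = FALSE] +
    64L * code[seq(4, npad, 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triple into a genotype panel
#'
#' Validates the bed magic bytes and the SNP-major mode byte, and checks
#' that the payload size matches `ceiling(N/4) * M`. Allele counts are
#' counts of the bim A1 allele; code 01 becomes `NA`.
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` files.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop_domain("missing PLINK file: %s", paste0(prefix, ext))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_domain("%s: not a PLINK bed file (bad magic bytes)", bed_path)
  if (raw[3] != as.raw(0x01))
    stop_domain("%s: only SNP-major bed files are supported", bed_path)
  bps <- ceiling(n / 4)           # bytes per SNP
  payload <- raw[-(1:3)]
  if (length(payload) != bps * m)
    stop_domain("%s: corrupt bed payload (%d bytes, expected %d for N=%d, M=%d)",
                bed_path, length(payload), bps * m, n, m)
  v <- as.integer(payload)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  counts <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], n, m)
  genotype_panel(counts, snp_ids = bim[[2]], chromosomes = bim[[1]],
                 positions = as.integer(bim[[4]]), sample_ids = fam[[2]])
}

#' Read a phenotype or covariate table
#'
#' Whitespace-delimited `FID IID V1 [V2 ...]` file, header optional.
#' Values are matched to the panel's individuals by IID when a panel is
#' given; `-9` and `NA` are treated as missing.
#'
#' @param path file path.
#' @param header does the file carry a header line?
#' @param panel optional [genotype_panel()] to align rows against.
#' @return A data frame with columns `fid`, `iid` and the value columns.
#' @export
read_pheno_table <- function(path, header = FALSE, panel = NULL) {
  tab <- utils::read.table(path, header = header)
  if (ncol(tab) < 3L) stop_domain("%s: expected FID IID V1 [V2 ...]", path)
  names(tab)[1:2] <- c("fid", "iid")
  if (!header) names(tab)[-(1:2)] <- paste0("V", seq_len(ncol(tab) - 2L))
  tab$iid <- as.character(tab$iid)
  for (j in seq(3L, ncol(tab)))
    tab[[j]] <- ifelse(tab[[j]] == -9, NA, as.numeric(tab[[j]]))
  if (!is.null(panel)) {
    i <- match(panel$sample_ids, tab$iid)
    if (anyNA(i))
      stop_domain("%s: %d panel individuals missing from file", path,
                  sum(is.na(i)))
    tab <- tab[i, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Write a 3-column phenotype file (FID IID PHENO)
#'
#' @param panel a [genotype_panel()] supplying the ids.
#' @param y numeric phenotype of length N.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(panel, y, path) {
  stopifnot(length(y) == nrow(panel$genotypes))
  utils::write.table(
    data.frame(panel$sample_ids, panel$sample_ids, y),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L)
    stop_domain("malformed region '%s'; expected chr:start-end", x)
  list(chr = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Filter a genotype panel by MAF, regions and SNP lists
#'
#' Retains SNPs with minor allele frequency strictly greater than
#' `maf_min` (the convention behind "MAF > 0.01"), outside every excluded
#' region (1-based inclusive `chr:start-end`, e.g. the MHC), and not named
#' in `exclude_snps`. SNP order is preserved and the operation is
#' idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min MAF threshold in \[0, 0.5).
#' @param exclude_regions character vector of `chr:start-end` regions.
#' @param exclude_snps character vector of SNP ids to drop.
#' @return A filtered [genotype_panel()]; warns if nothing survives.
#' @export
filter_panel <- function(panel, maf_min = 0, exclude_regions = NULL,
                         exclude_snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (maf_min < 0 || maf_min >= 0.5)
    stop_domain("maf_min must lie in [0, 0.5)")
  maf <- pmin(panel$allele_freq, 1 - panel$allele_freq)
  keep <- maf > maf_min
  for (r in lapply(exclude_regions, parse_region)) {
    inside <- panel$chromosomes == r$chr &
      panel$positions >= r$start & panel$positions <= r$end
    keep <- keep & !inside
  }
  if (!is.null(exclude_snps)) keep <- keep & !(panel$snp_ids %in% exclude_snps)
  if (!any(keep)) warning("filter removed every SNP")
  subset_panel(panel, snps = keep)
}
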