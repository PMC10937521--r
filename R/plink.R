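# PLINK 1 binary fileset support. The .bed payload is variant-major, two bits
# per genotype, LSB first within each byte:
#   00 -> homozygous allele1 (dosage 2)   10 -> heterozygous (dosage 1)
#   11 -> homozygous allele2 (dosage 0)   01 -> missing call (NA)
# Dosage is the count of allele1; the writer leaves alleles as stored, and
# recode_minor_allele() flips columns so allele1 is the minor allele.

BED_MAGIC <- as.raw(c(0x6C, 0x1B))
BED_VARIANT_MAJOR <- as.raw(0x01)

# byte value (0..255) -> 4 dosages, LSB-first; row b+1 decodes byte b
bed_decode_table <- function() {
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L) # codes 00, 01, 10, 11
  b <- 0:255
  cbind(code_to_dosage[b %% 4L + 1L],
        code_to_dosage[(b %/% 4L) %% 4L + 1L],
        code_to_dosage[(b %/% 16L) %% 4L + 1L],
        code_to_dosage[(b %/% 64L) %% 4L + 1L])
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes `<prefix>.bed` / `.bim` / `.fam` into a [geno_block()]. Only the
#' variant-major dialect (mode byte `0x01`) is supported; sample and variant
#' order follow the files.
#'
#' @param prefix Path prefix of the fileset (no extension).
#' @return A [geno_block()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths))) {
    abort(sprintf("missing PLINK files for prefix '%s'", prefix))
  }
  bim <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  names(fam) <- c("fid", "sample_id", "pid", "mid", "sex", "pheno")[seq_len(ncol(fam))]
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.info(paths[1])$size)
  if (length(raw) < 3 || !identical(raw[1:2], BED_MAGIC)) {
    abort(".bed file lacks the PLINK 1 magic bytes")
  }
  if (!identical(raw[3], BED_VARIANT_MAJOR)) {
    abort("only variant-major .bed files (mode byte 0x01) are supported")
  }
  bpv <- ceiling(n / 4)
  if (length(raw) != 3 + bpv * m) {
    abort(sprintf(".bed payload is %d bytes; expected %d for %d samples x %d variants",
                  length(raw) - 3, bpv * m, n, m))
  }
  lut <- bed_decode_table()
  body <- as.integer(raw[-(1:3)])
  # decode all bytes to a (4*bpv) x m dosage matrix, then trim padding rows
  decoded <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = 4L * bpv)
  geno <- decoded[seq_len(n), , drop = FALSE]
  geno_block(geno, variants = tibble::as_tibble(bim),
             samples = tibble::tibble(sample_id = fam$sample_id))
}

#' Write a PLINK 1 binary fileset
#'
#' Emits variant-major `.bed`, tab-separated `.bim` (chrom, id, cM, pos,
#' allele1, allele2) and `.fam` files. Round-trips bit-exactly through
#' [read_plink()], including missing calls.
#'
#' @param block A [geno_block()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(block, prefix) {
  stopifnot(inherits(block, "geno_block"))
  if (anyDuplicated(block$variants$id)) abort("duplicate variant ids")
  g <- block$geno
  n <- nrow(g)
  m <- ncol(g)
  bpv <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(3L, nrow = n, ncol = m)
  code[!is.na(g) & g == 2L] <- 0L
  code[!is.na(g) & g == 1L] <- 2L
  code[is.na(g)] <- 1L
  padded <- matrix(0L, nrow = 4L * bpv, ncol = m)
  if (n > 0) padded[seq_len(n), ] <- code
  shifts <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bpv, ncol = m)
  for (s in 1:4) {
    bytes <- bytes + padded[seq(s, 4L * bpv, by = 4L), , drop = FALSE] * shifts[s]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_VARIANT_MAJOR, as.raw(bytes)), con)
  utils::write.table(block$variants[, c("chrom", "id", "cm", "pos", "a1", "a2")],
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = block$samples$sample_id,
                    iid = block$samples$sample_id,
                    pid = 0L, mid = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Recode alleles so allele1 is the minor allele
#'
#' Flips any variant whose allele1 frequency exceeds 0.5 (on non-missing
#' calls): dosages become `2 - dosage` and the allele columns swap, so that
#' dosage = minor-allele count, the convention assumed downstream.
#'
#' @param block A [geno_block()].
#' @return The recoded [geno_block()].
#' @export
recode_minor_allele <- function(block) {
  g <- block$geno
  af <- colMeans(g, na.rm = TRUE) / 2
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) {
    g[, flip] <- 2L - g[, flip]
    v <- block$variants
    tmp <- v$a1[flip]
    v$a1[flip] <- v$a2[flip]
    v$a2[flip] <- tmp
    block <- geno_block(g, variants = v, samples = block$samples)
  }
  block
}

#' Write a node's phenotype/covariate table
#'
#' @param node A [node_data()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(node, path) {
  utils::write.table(node$pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
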