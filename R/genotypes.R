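#' Genotype container
#'
#' Bundles a calls matrix (individuals in rows, variants in columns, values
#' 0/1/2 counting copies of the minor allele, `NA` for a missing call) with a
#' variant table and a sample table. This is the object every downstream
#' stage (QC, LD pruning, ROH calling, F statistics) consumes.
#'
#' @param calls integer matrix, individuals x variants; entries 0, 1, 2 or NA.
#' @param variants data.frame with columns `chrom`, `id`, `cm`, `bp`, `a1`,
#'   `a2`; `bp` (1-based) must be strictly increasing within each chromosome.
#' @param samples data.frame with columns `fid`, `iid`, `sex` (1 = male,
#'   2 = female, 0 = unknown); further covariate columns are carried along.
#' @return An object of class `genotypes`: a list with elements `calls`,
#'   `variants`, `samples`.
#' @examples
#' g <- genotypes(
#'   calls = matrix(c(0L, 1L, 2L, 1L), 2, 2),
#'   variants = data.frame(chrom = 1, id = c("s1", "s2"), cm = 0,
#'                         bp = c(100L, 200L), a1 = "A", a2 = "G"),
#'   samples = data.frame(fid = c("f1", "f2"), iid = c("i1", "i2"),
#'                        sex = c(1L, 2L))
#' )
#' g
#' @export
genotypes <- function(calls, variants, samples) {
  if (!is.matrix(calls)) abort_autozyg("`calls` must be a matrix", "autozyg_type_error")
  storage.mode(calls) <- "integer"
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) {
    abort_autozyg("`calls` entries must be 0, 1, 2 or NA", "autozyg_type_error")
  }
  required_v <- c("chrom", "id", "bp", "a1", "a2")
  if (!all(required_v %in% names(variants))) {
    abort_autozyg(
      paste("`variants` must have columns", paste(required_v, collapse = ", ")),
      "autozyg_type_error"
    )
  }
  if (is.null(variants$cm)) variants$cm <- 0
  if (!all(c("fid", "iid", "sex") %in% names(samples))) {
    abort_autozyg("`samples` must have columns fid, iid, sex", "autozyg_type_error")
  }
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls)) {
    abort_autozyg(
      sprintf(
        "dimension mismatch: %d x %d calls vs %d samples, %d variants",
        nrow(calls), ncol(calls), nrow(samples), nrow(variants)
      ),
      "autozyg_integrity_error"
    )
  }
  if (anyDuplicated(samples$iid)) {
    abort_autozyg("sample ids must be unique", "autozyg_integrity_error")
  }
  for (ch in unique(variants$chrom)) {
    bp <- variants$bp[variants$chrom == ch]
    if (any(diff(bp) <= 0)) {
      abort_autozyg(
        sprintf("bp positions must be strictly increasing within chromosome %s", ch),
        "autozyg_integrity_error"
      )
    }
  }
  rownames(calls) <- samples$iid
  colnames(calls) <- variants$id
  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat(sprintf(
    "<genotypes> %d individuals x %d variants (%d chromosome%s), %.3f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1L) "" else "s",
    100 * n_miss / length(x$calls)
  ))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' Subset a genotype object by individuals and/or variants
#'
#' @param x a `genotypes` object.
#' @param i individual index (logical, integer or character iid).
#' @param j variant index (logical, integer or character id).
#' @param ... ignored.
#' @return A `genotypes` object restricted to the selected rows/columns.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$iid)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotypes(
    calls = x$calls[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE]
  )
}

# ---- PLINK 1 binary codec -------------------------------------------------
#
# .bed stores genotypes SNP-major, 4 individuals per byte, 2 bits each
# (low bits first): 00 = homozygous A1, 01 = missing, 10 = heterozygous,
# 11 = homozygous A2. A1 is written as the minor allele, so on our 0/1/2
# minor-allele-count scale: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# per-variant integer codes for one packed column of individuals
encode_bed_codes <- function(calls_col) {
  code <- integer(length(calls_col))
  code[is.na(calls_col)] <- 1L
  code[!is.na(calls_col) & calls_col == 2L] <- 0L
  code[!is.na(calls_col) & calls_col == 1L] <- 2L
  code[!is.na(calls_col) & calls_col == 0L] <- 3L
  code
}

#' Write genotypes as a PLINK 1 binary fileset
#'
#' Emits `prefix.bed` (SNP-major, standard 2-bit encoding), `prefix.bim` and
#' `prefix.fam`.
#'
#' @param g a `genotypes` object.
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @seealso [read_plink()]
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  n <- nrow(g$calls)
  m <- ncol(g$calls)
  bytes_per_variant <- ceiling(n / 4)
  # pack the whole matrix at once: pad individuals to a multiple of 4
  codes <- apply(g$calls, 2L, encode_bed_codes)
  codes <- matrix(as.integer(codes), nrow = n, ncol = m)
  pad <- bytes_per_variant * 4L - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  i1 <- seq(1L, nrow(codes), by = 4L)
  packed <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] +
    64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(as.vector(packed)), con)

  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$id, v$cm, v$bp, v$a1, v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  s <- g$samples
  fam <- data.frame(
    fid = s$fid, iid = s$iid,
    pat = s$pat %||% 0, mat = s$mat %||% 0,
    sex = s$sex, phe = s$phe %||% -9
  )
  utils::write.table(fam, paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes `prefix.bed`/`.bim`/`.fam` into a [genotypes()] object. Only the
#' SNP-major layout (the only layout modern tools emit) is supported; the
#' magic bytes and the payload size are checked before decoding. Genotypes
#' are returned as counts of the A1 allele with the PLINK missing code
#' mapped to `NA`; variant order is preserved from the `.bim` file.
#'
#' @param prefix path prefix of the fileset (no extension).
#' @return A `genotypes` object.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort_autozyg(paste("missing file:", f), "autozyg_io_error")
  }
  variants <- utils::read.table(bim,
    col.names = c("chrom", "id", "cm", "bp", "a1", "a2"),
    colClasses = c("character", "character", "numeric", "integer", "character", "character")
  )
  samples <- utils::read.table(fam,
    col.names = c("fid", "iid", "pat", "mat", "sex", "phe"),
    colClasses = c("character", "character", "character", "character", "integer", "numeric")
  )
  n <- nrow(samples)
  m <- nrow(variants)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC[1:2])) {
    abort_autozyg("not a PLINK .bed file (bad magic bytes)", "autozyg_format_error")
  }
  if (raw[3] != BED_MAGIC[3]) {
    abort_autozyg("only SNP-major .bed files are supported", "autozyg_format_error")
  }
  bytes_per_variant <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_variant * m) {
    abort_autozyg(
      sprintf(
        ".bed payload has %d bytes, expected %d for %d individuals x %d variants",
        length(payload), bytes_per_variant * m, n, m
      ),
      "autozyg_integrity_error"
    )
  }
  b <- as.integer(payload)
  # unpack 4 two-bit codes per byte, low bits first
  codes <- rbind(
    b %% 4L,
    (b %/% 4L) %% 4L,
    (b %/% 16L) %% 4L,
    (b %/% 64L) %% 4L
  )
  codes <- matrix(as.vector(codes), nrow = bytes_per_variant * 4L, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  calls[codes == 0L] <- 2L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 0L
  genotypes(calls, variants, samples)
}

# ---- delimited tables -----------------------------------------------------

roh_table_cols <- c("iid", "chrom", "start_bp", "end_bp", "n_snps", "length_kb")

#' Write a table of ROH segments as TSV
#'
#' One row per segment: individual id, chromosome, start/end bp (1-based,
#' inclusive), SNP count, and length in kb under the `end - start + 1`
#' convention used throughout the package.
#'
#' @param segments a `roh_segments` data.frame as returned by [call_roh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roh_table <- function(segments, path) {
  df <- data.frame(
    iid = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), n_snps = integer(0), length_kb = numeric(0)
  )
  if (nrow(segments)) {
    df <- data.frame(
      iid = as.character(segments$iid),
      chrom = as.character(segments$chrom),
      start_bp = segments$start_bp,
      end_bp = segments$end_bp,
      n_snps = segments$n_snps,
      length_kb = (segments$end_bp - segments$start_bp + 1) / 1000
    )
  }
  ok <- tryCatch(
    {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    },
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok) abort_autozyg(paste("cannot write", path), "autozyg_io_error")
  invisible(path)
}

#' Read a table of ROH segments written by [write_roh_table()]
#'
#' @param path TSV file path.
#' @return A `roh_segments` data.frame with a recomputed `length_bp` column.
#' @export
read_roh_table <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "integer", "integer", "integer", "numeric")
  )
  if (!identical(names(df), roh_table_cols)) {
    abort_autozyg("unexpected ROH table columns", "autozyg_format_error")
  }
  df$length_bp <- df$end_bp - df$start_bp + 1
  class(df) <- c("roh_segments", "data.frame")
  df
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with a header; the first column must be `iid`.
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (names(df)[1] != "iid") {
    abort_autozyg("phenotype table must start with an `iid` column", "autozyg_format_error")
  }
  df
}

#' Write a phenotype/covariate table as TSV
#'
#' @param pheno data.frame whose first column is `iid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
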