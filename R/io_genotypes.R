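# Genotype readers/writers: PLINK bed/bim/fam and a plain-text dialect.

#' Read genotypes from PLINK bed/bim/fam or the text dialect
#'
#' For \code{format = "plink-bed"}, \code{path} is the \code{.bed} file (or its
#' stem) and the companion \code{.bim}/\code{.fam} files must sit next to it.
#' Only SNP-major v1.00 files (magic bytes 0x6c 0x1b 0x01) are accepted.
#' Counts refer to allele 1 of the .bim: byte code 00 = 2 copies, 10 = 1,
#' 11 = 0, 01 = missing. Sample order is preserved from the .fam.
#'
#' The text dialect is: optional \code{##variant id chrom pos a1 a2} comment
#' lines, a header row \code{FID IID <variant ids...>}, then one row per
#' individual with counts (NA for missing), whitespace-delimited.
#'
#' @param path file path (.bed, stem, or text file).
#' @param format "plink-bed" or "text".
#' @return \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("plink-bed", "text")) {
  format <- match.arg(format)
  if (format == "text") read_genotypes_text(path) else read_plink_bed(path)
}

#' Write genotypes to PLINK bed/bim/fam or the text dialect
#' @param geno genotype_matrix.
#' @param path output path: .bed path or stem for plink-bed, file path for
#'   text.
#' @param format "plink-bed" or "text".
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(geno, path, format = c("plink-bed", "text")) {
  format <- match.arg(format)
  if (format == "text") write_genotypes_text(geno, path)
  else write_plink_bed(geno, path)
}

plink_stem <- function(path) sub("\\.bed$", "", path)

read_plink_bed <- function(path) {
  stem <- plink_stem(path)
  bed <- paste0(stem, ".bed")
  bim <- paste0(stem, ".bim")
  fam <- paste0(stem, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) dn_stop("read_genotypes: missing file %s", f)

  bimdf <- utils::read.table(bim, header = FALSE,
                             col.names = c("chrom", "id", "cm", "pos",
                                           "a1", "a2"),
                             colClasses = c("character", "character",
                                            "numeric", "integer",
                                            "character", "character"))
  famdf <- utils::read.table(fam, header = FALSE,
                             colClasses = "character")[, 1:2]
  names(famdf) <- c("fid", "iid")
  n <- nrow(famdf)
  m <- nrow(bimdf)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    dn_stop("read_genotypes: %s has malformed magic bytes", bed)
  if (raw[3] != as.raw(0x01))
    dn_stop("read_genotypes: %s is not SNP-major v1.00", bed)
  bpv <- ceiling(n / 4)                      # bytes per variant
  body <- raw[-(1:3)]
  if (length(body) != bpv * m)
    dn_stop("read_genotypes: %s has %d data bytes, expected %d (n=%d, m=%d)",
            bed, length(body), bpv * m, n, m)

  # decode all two-bit fields at once via a 256 x 4 lookup of allele-1 counts
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) for (s in 1:4) {
    code <- bitwAnd(bitwShiftR(b, 2L * (s - 1L)), 3L)
    lut[b + 1L, s] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
  }
  ints <- as.integer(body) + 1L
  dec <- lut[ints, ]                          # (bpv*m) x 4 allele-1 counts
  dim(dec) <- c(bpv, m, 4)
  counts <- matrix(NA_integer_, n, m)
  for (s in 1:4) {
    rows <- seq.int(s, by = 4L, length.out = bpv)
    keep <- rows <= n
    counts[rows[keep], ] <- dec[which(keep), , s]
  }
  genotype_matrix(counts, bimdf[, c("chrom", "id", "pos", "a1", "a2")], famdf)
}

write_plink_bed <- function(geno, path) {
  stem <- plink_stem(path)
  n <- nrow(geno$counts)
  m <- ncol(geno$counts)
  v <- geno$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2),
    paste0(stem, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$samples$fid, geno$samples$iid, 0, 0, 0, -9),
    paste0(stem, ".fam"), quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)

  code <- matrix(1L, nrow = n, ncol = m)      # 01 = missing
  cnt <- geno$counts
  code[!is.na(cnt) & cnt == 2L] <- 0L         # 00 = hom allele 1
  code[!is.na(cnt) & cnt == 1L] <- 2L         # 10 = het
  code[!is.na(cnt) & cnt == 0L] <- 3L         # 11 = hom allele 2
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  shifts <- 2L * (0:3)
  bytes <- integer(bpv * m)
  dim(code) <- c(4, bpv * m)
  for (s in 1:4) bytes <- bytes + bitwShiftL(code[s, ], shifts[s])
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(stem, c(".bed", ".bim", ".fam")))
}

read_genotypes_text <- function(path) {
  if (!file.exists(path)) dn_stop("read_genotypes: missing file %s", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##variant")]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) dn_stop("read_genotypes: %s is empty", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(header) < 3 || header[1] != "FID" || header[2] != "IID")
    dn_stop("read_genotypes: %s header must start with FID IID", path)
  ids <- header[-(1:2)]
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  nc <- lengths(body)
  if (any(nc != length(header)))
    dn_stop("read_genotypes: %s row %d has %d fields, expected %d",
            path, which(nc != length(header))[1] + 1,
            nc[nc != length(header)][1], length(header))
  tab <- do.call(rbind, body)
  counts <- suppressWarnings(
    matrix(as.integer(tab[, -(1:2), drop = FALSE]),
           nrow = nrow(tab)))
  bad <- is.na(counts) & tab[, -(1:2), drop = FALSE] != "NA"
  if (any(bad))
    dn_stop("read_genotypes: %s has a non-integer count at data row %d",
            path, which(rowSums(bad) > 0)[1])
  variants <- data.frame(chrom = "0", id = ids,
                         pos = seq_along(ids), a1 = "A", a2 = "B",
                         stringsAsFactors = FALSE)
  if (length(meta)) {
    mm <- do.call(rbind, strsplit(trimws(sub("^##variant\\s+", "", meta)),
                                  "[ \t]+"))
    idx <- match(mm[, 1], ids)
    ok <- !is.na(idx)
    variants$chrom[idx[ok]] <- mm[ok, 2]
    variants$pos[idx[ok]] <- as.integer(mm[ok, 3])
    variants$a1[idx[ok]] <- mm[ok, 4]
    variants$a2[idx[ok]] <- mm[ok, 5]
  }
  genotype_matrix(counts, variants,
                  data.frame(fid = tab[, 1], iid = tab[, 2],
                             stringsAsFactors = FALSE))
}

write_genotypes_text <- function(geno, path) {
  v <- geno$variants
  meta <- sprintf("##variant %s %s %d %s %s", v$id, v$chrom, v$pos, v$a1, v$a2)
  header <- paste(c("FID", "IID", v$id), collapse = " ")
  cnt <- geno$counts
  cnt[is.na(cnt)] <- NA
  body <- apply(cbind(geno$samples$fid, geno$samples$iid,
                      ifelse(is.na(cnt), "NA", as.character(cnt))),
                1, paste, collapse = " ")
  writeLines(c(meta, header, body), path)
  invisible(path)
}
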