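# PLINK 1 binary triple (.bed/.bim/.fam) and a headerless text dialect.
# SNP-major .bed only; 2-bit fields, 4 subjects per byte, low-order bits
# first: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_CODE_TO_GENO <- c(2L, NA_integer_, 1L, 0L)   # index = 2-bit code + 1
BED_GENO_TO_CODE <- c(3L, 2L, 0L)                # index = genotype + 1; NA -> 1

#' Read a PLINK 1 binary fileset
#'
#' Decodes a SNP-major `.bed/.bim/.fam` triple into a bit-packed
#' [genotype_matrix()] and a [phenotype()].  Genotypes are recoded to
#' minor-allele counts, with the minor allele determined per SNP from the
#' full sample (ties kept at the .bim A1 allele); allele labels are swapped
#' consistently when a SNP is flipped.  Subjects with a .fam phenotype
#' outside \{1, 2\} (e.g. 0 or -9) are excluded with a warning.
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read.  Ignored if
#'   the explicit paths are given.
#' @param bed,bim,fam explicit file paths.
#' @param recode_minor recode genotypes to minor-allele counts (default);
#'   set `FALSE` to count the .bim A1 allele as stored.
#' @return `list(genotypes = genotype_matrix, phenotype = phenotype)`.
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL,
                       recode_minor = TRUE) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f))
      stop(new_error("treemwu_io_error", paste("file not found:", f)))

  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  names(bim_df) <- c("chr", "id", "cm", "pos", "a1", "a2")[seq_len(ncol(bim_df))]
  n0 <- nrow(fam_df)
  p <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC))
    stop(new_error("treemwu_format_error",
                   paste0(bed, ": not a PLINK .bed file (bad magic bytes)")))
  if (raw[3L] == as.raw(0x00))
    stop(new_error("treemwu_format_error",
                   paste0(bed, ": individual-major .bed files are not supported")))
  if (raw[3L] != as.raw(0x01))
    stop(new_error("treemwu_format_error",
                   paste0(bed, ": unknown .bed mode byte")))
  bpf <- as.integer(ceiling(n0 / 4))
  if (length(raw) != 3L + bpf * p)
    stop(new_error("treemwu_format_error",
                   sprintf("%s: expected %d data bytes, found %d",
                           bed, bpf * p, length(raw) - 3L)))

  bits <- as.integer(rawToBits(raw[-(1:3)]))
  codes <- bits[c(TRUE, FALSE)] + 2L * bits[c(FALSE, TRUE)]
  g <- matrix(BED_CODE_TO_GENO[codes + 1L], nrow = 4L * bpf)[seq_len(n0), ,
                                                             drop = FALSE]

  ph_raw <- fam_df[[6L]]
  keep <- ph_raw %in% c(1, 2)
  if (!all(keep))
    warning(sprintf("excluding %d subject(s) with phenotype outside {1,2}",
                    sum(!keep)))
  if (!any(keep))
    stop(new_error("treemwu_phenotype_error", "no subjects with valid phenotype"))
  g <- g[keep, , drop = FALSE]
  fam_df <- fam_df[keep, , drop = FALSE]

  if (recode_minor) {
    a1_freq <- colMeans(g, na.rm = TRUE) / 2
    flip <- !is.na(a1_freq) & a1_freq > 0.5
    if (any(flip)) {
      g[, flip] <- 2L - g[, flip]
      tmp <- bim_df$a1[flip]
      bim_df$a1[flip] <- bim_df$a2[flip]
      bim_df$a2[flip] <- tmp
    }
  }

  sub_ids <- as.character(fam_df[[2L]])
  if (anyDuplicated(sub_ids))
    sub_ids <- paste(fam_df[[1L]], fam_df[[2L]], sep = ":")
  gm <- genotype_matrix(g, snp_ids = bim_df$id, subject_ids = sub_ids,
                        a1 = bim_df$a1, a2 = bim_df$a2, map = bim_df)
  ph <- phenotype(as.integer(ph_raw[keep] == 2), subject_ids = sub_ids)
  list(genotypes = gm, phenotype = ph)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes a SNP-major `.bed/.bim/.fam` triple readable by [read_plink()].
#' Pad bits beyond the last subject are zero.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a [phenotype()] aligned with `gm`, or a plain 0/1 status
#'   vector (fixtures need not contain both classes).
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(gm, ph, prefix) {
  if (!inherits(ph, "phenotype"))
    ph <- list(status = as.integer(ph))
  stopifnot(inherits(gm, "genotype_matrix"),
            length(ph$status) == gm$n_subjects,
            all(ph$status %in% 0:1))
  g <- geno(gm)
  n <- gm$n_subjects
  p <- gm$n_snps
  bpf <- as.integer(ceiling(n / 4))

  code <- matrix(1L, 4L * bpf, p)              # pad defaults overwritten below
  gc <- BED_GENO_TO_CODE[g + 1L]
  gc[is.na(g)] <- 1L
  code[seq_len(n), ] <- gc
  code[setdiff(seq_len(4L * bpf), seq_len(n)), ] <- 0L
  bits <- rbind(as.vector(code) %% 2L, as.vector(code) %/% 2L)
  bed_path <- paste0(prefix, ".bed")
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, as.raw(0x01), packBits(as.logical(bits), "raw")), con)

  map <- gm$map
  if (is.null(map))
    map <- data.frame(chr = 1L, id = gm$snp_ids, cm = 0L, pos = seq_len(p),
                      a1 = gm$a1 %||% rep("A", p), a2 = gm$a2 %||% rep("B", p))
  bim_path <- paste0(prefix, ".bim")
  write.table(map, bim_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam_path <- paste0(prefix, ".fam")
  fam <- data.frame(fid = gm$subject_ids, iid = gm$subject_ids,
                    pid = 0L, mid = 0L, sex = 0L, pheno = ph$status + 1L)
  write.table(fam, fam_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}

#' Read the text genotype dialect
#'
#' Headerless whitespace-delimited rows, one per subject:
#' `FID IID phenotype g1 g2 ...` with genotypes coded 0/1/2 and a missing
#' token (default `"NA"`).  Phenotype 2 = case, 1 = control; -9 or 0
#' excludes the subject with a warning.
#'
#' @param path file path.
#' @param missing_code token standing for a missing genotype.
#' @param snp_ids optional SNP names; defaults to `SNP1..SNPp`.
#' @return `list(genotypes = genotype_matrix, phenotype = phenotype)`.
#' @export
read_geno_text <- function(path, missing_code = "NA", snp_ids = NULL) {
  if (!file.exists(path))
    stop(new_error("treemwu_io_error", paste("file not found:", path)))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(new_error("treemwu_format_error", paste(path, "is empty")))
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (any(len != len[1L]))
    stop(new_error("treemwu_format_error",
                   sprintf("%s: row %d has %d fields, expected %d", path,
                           which(len != len[1L])[1L],
                           len[which(len != len[1L])[1L]], len[1L])))
  if (len[1L] < 4L)
    stop(new_error("treemwu_format_error",
                   "text rows need FID, IID, phenotype and >= 1 genotype"))
  m <- do.call(rbind, toks)
  fid <- m[, 1L]
  iid <- m[, 2L]
  ph_tok <- m[, 3L]
  gt <- m[, -(1:3), drop = FALSE]

  bad <- matrix(!(gt %in% c("0", "1", "2", missing_code)), nrow(gt))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(new_error("treemwu_format_error",
                   sprintf("%s: unknown genotype token \"%s\" (row %d, SNP %d)",
                           path, gt[bad][1L], w[1L], w[2L])))
  }
  g <- matrix(NA_integer_, nrow(gt), ncol(gt))
  g[gt != missing_code] <- as.integer(gt[gt != missing_code])

  keep <- ph_tok %in% c("1", "2")
  if (!all(keep))
    warning(sprintf("excluding %d subject(s) with phenotype outside {1,2}",
                    sum(!keep)))
  if (!any(keep))
    stop(new_error("treemwu_phenotype_error", "no subjects with valid phenotype"))
  g <- g[keep, , drop = FALSE]
  ids <- iid[keep]
  if (anyDuplicated(ids)) ids <- paste(fid[keep], ids, sep = ":")
  gm <- genotype_matrix(g, snp_ids = snp_ids, subject_ids = ids)
  ph <- phenotype(as.integer(ph_tok[keep] == "2"), subject_ids = ids)
  list(genotypes = gm, phenotype = ph)
}

#' Write the text genotype dialect
#'
#' @inheritParams write_plink
#' @param path output file path.
#' @param missing_code token written for missing genotypes.
#' @export
write_geno_text <- function(gm, ph, path, missing_code = "NA") {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(ph, "phenotype"))
  g <- geno(gm)
  gt <- matrix(as.character(g), nrow(g), ncol(g))
  gt[is.na(g)] <- missing_code
  out <- cbind(gm$subject_ids, gm$subject_ids, ph$status + 1L, gt)
  writeLines(apply(out, 1L, paste, collapse = " "), path)
  invisible(path)
}
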