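# Forward-selection risk-group tree shared by LRMW and TAMW.
#
# Each level adds one SNP and one genotype partition, applied to every
# current risk group simultaneously, so depth d induces up to 2^d groups.
# The (SNP, partition) pair at each level is the greedy argmax of the MWU
# of the resulting plug-in LR assignment.

PARTITION_TABLE <- data.frame(
  code = 0:2,
  low = c("0", "0,1", "1"),
  high = c("1,2", "2", "0,2"),
  stringsAsFactors = FALSE
)

#' Allowed genotype partitions
#'
#' Without the heterozygote option the dominant and recessive partitions
#' `{0}|{1,2}` and `{0,1}|{2}`; with `hz = TRUE` also the
#' heterozygote-vs-homozygotes partition `{1}|{0,2}`.
#'
#' @param hz include the heterozygote effect (Aa vs AA/aa)?
#' @return Data frame with columns `code`, `low`, `high`, in the fixed
#'   tie-break order.
#' @export
enumerate_partitions <- function(hz = FALSE) {
  PARTITION_TABLE[seq_len(if (isTRUE(hz)) 3L else 2L), ]
}

# Side of genotype g under a partition code: 0 = low, 1 = high, NA missing.
partition_side <- function(g, code) {
  switch(code + 1L,
         as.integer(g != 0L),
         as.integer(g > 1L),
         as.integer(g != 1L))
}

#' Grow a forward-selection risk-group tree
#'
#' Greedy level-wise search: at each level every (candidate SNP, allowed
#' partition) pair is scored by refining all current risk groups with that
#' split, assigning plug-in likelihood ratios to the refined groups, and
#' computing the MWU of the full assignment; the argmax is kept.  Growth
#' stops at `max_depth`, when no split keeps every nonempty refined group at
#' `min_group_size` or more, or when no split strictly increases U (beyond a
#' 1e-12 floating-point guard).  A SNP is used at most once.  Subjects
#' missing the chosen SNP at a level keep the LR of their pre-split group
#' and leave the refined groups' counts.
#'
#' @param gm a [genotype_matrix()] (or a plain 0/1/2/NA integer matrix).
#' @param ph a [phenotype()] aligned with the rows of `gm`.
#' @param candidate_snps SNP ids or column indices to search (default: all).
#' @param max_depth maximum number of SNPs (levels).
#' @param min_group_size smallest admissible risk group (default 10).
#' @param hz include the heterozygote partition?
#' @param smoothing additive smoothing for leaf LRs (default 0.5).
#' @param subjects optional subject row indices to train on (repeats
#'   allowed, e.g. a bootstrap sample).
#' @return Object of class `risk_group_tree`.
#' @export
grow_tree <- function(gm, ph, candidate_snps = NULL, max_depth = 1L,
                      min_group_size = 10L, hz = FALSE, smoothing = 0.5,
                      subjects = NULL) {
  g <- as_geno_int(gm)
  snp_ids <- colnames(g) %||% paste0("SNP", seq_len(ncol(g)))
  stopifnot(max_depth >= 1L, min_group_size >= 1L, smoothing >= 0)
  cand <- sort(resolve_idx(candidate_snps, snp_ids))
  if (!length(cand))
    stop(new_error("treemwu_format_error", "no candidate SNPs"))
  rows <- if (is.null(subjects)) seq_len(nrow(g)) else as.integer(subjects)
  status <- ph$status[rows]
  if (sum(status) < 1L || sum(1L - status) < 1L)
    stop(new_error("treemwu_phenotype_error",
                   "training subjects must include a case and a control"))
  parts <- enumerate_partitions(hz)$code

  res <- cpp_grow_tree(g, rows, status, cand, as.integer(max_depth),
                       as.integer(min_group_size), as.integer(parts),
                       smoothing, 1e-12)
  if (!length(res$snp))
    stop(new_error("treemwu_empty_tree",
                   "no admissible first split (check min_group_size and candidate SNPs)"))
  structure(list(
    depth = length(res$snp),
    snp_index = res$snp,
    snp_ids = snp_ids[res$snp],
    part_codes = res$part,
    partitions = PARTITION_TABLE[res$part + 1L, ],
    levels = res$levels,
    u_path = res$u_path,
    u_root = 0.5,
    min_group_size = as.integer(min_group_size),
    smoothing = smoothing,
    hz = isTRUE(hz),
    n_case = sum(status),
    n_control = sum(1L - status),
    training = list(lr = res$subject_lr, group = res$subject_group,
                    frozen = res$subject_frozen, rows = rows)
  ), class = "risk_group_tree")
}

#' Assign likelihood ratios by routing subjects through a tree
#'
#' Each subject is routed by its genotypes at the tree's SNPs; its score is
#' the training LR of the group it lands in.  A subject hitting a missing
#' genotype stops at its current group and keeps that group's LR (the root
#' LR is 1).  A subject routed to a genotype combination unobserved in
#' training keeps the parent group's LR and is flagged.
#'
#' @param tree a [grow_tree()] result.
#' @param gm genotype data for the subjects to score.
#' @param subjects optional subject selection (indices into `gm`).
#' @param depth route only through the first `depth` levels (defaults to
#'   the full tree); used for cross-validated depth selection.
#' @return Object of class `lr_assignment`: `lr` (scores), `group` (final
#'   group index per subject, `NA` once routing stopped), `flagged`
#'   (unobserved-combination fallback).
#' @export
assign_lr <- function(tree, gm, subjects = NULL, depth = tree$depth) {
  stopifnot(inherits(tree, "risk_group_tree"), depth >= 0L,
            depth <= tree$depth)
  g <- as_geno_int(gm)
  if (!is.null(subjects)) g <- g[as.integer(subjects), , drop = FALSE]
  m <- nrow(g)
  grp <- rep(0L, m)
  lr <- rep(1, m)
  active <- rep(TRUE, m)
  flagged <- rep(FALSE, m)
  for (d in seq_len(depth)) {
    sd <- partition_side(g[, tree$snp_index[d]], tree$part_codes[d])
    idx <- which(active)
    sdx <- sd[idx]
    active[idx[is.na(sdx)]] <- FALSE            # missing: stay at parent
    idx <- idx[!is.na(sdx)]
    sdx <- sdx[!is.na(sdx)]
    ng <- 2L * grp[idx] + sdx
    new_lr <- tree$levels[[d]]$lr[ng + 1L]
    unseen <- is.na(new_lr)
    flagged[idx[unseen]] <- TRUE                # fall back to parent LR
    active[idx[unseen]] <- FALSE
    keep <- !unseen
    grp[idx[keep]] <- ng[keep]
    lr[idx[keep]] <- new_lr[keep]
  }
  structure(list(lr = lr, group = grp, flagged = flagged, depth = depth),
            class = "lr_assignment")
}

#' @export
print.risk_group_tree <- function(x, ...) {
  cat(sprintf("risk_group_tree: depth %d, %d cases / %d controls, training U = %.4f\n",
              x$depth, x$n_case, x$n_control, x$u_path[x$depth]))
  for (d in seq_len(x$depth)) {
    lv <- x$levels[[d]]
    nz <- which(!is.na(lv$lr))
    cat(sprintf("  level %d: %s  [%s | %s]  groups: %s\n", d, x$snp_ids[d],
                x$partitions$low[d], x$partitions$high[d],
                paste(sprintf("%d:%d/%d LR=%.3g", nz - 1L, lv$n_case[nz],
                              lv$n_control[nz], lv$lr[nz]), collapse = "  ")))
  }
  invisible(x)
}

# Machine-readable tree summary for reports.
tree_summary <- function(tree) {
  lapply(seq_len(tree$depth), function(d) {
    lv <- tree$levels[[d]]
    nz <- which(!is.na(lv$lr))
    list(snp = tree$snp_ids[d],
         partition = paste0("{", tree$partitions$low[d], "}|{",
                            tree$partitions$high[d], "}"),
         training_u = tree$u_path[d],
         groups = data.frame(group = nz - 1L, n_case = lv$n_case[nz],
                             n_control = lv$n_control[nz], lr = lv$lr[nz]))
  })
}
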