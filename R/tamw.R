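# TAMW: bootstrap ensemble of de-correlated forward-selection trees.
#
# Each tree is grown on a bootstrap sample, restricted to a random subset
# of mtry SNPs, and applied to its out-of-bag (OOB) subjects; per-subject
# OOB LR values are averaged into the assembled score
# LR_assem_i = sum_j LR_{i,j} / T_i, which the MWU then tests.  A burn-in
# phase fixes the tree depth: the first `burnin` trees are evaluated at
# every depth in `depth_grid` and the depth with the best accumulated OOB
# U is used for the whole ensemble.

#' Fit the TAMW ensemble
#'
#' @inheritParams grow_tree
#' @param n_trees number of bootstrap trees (default 500).
#' @param mtry SNPs offered to each tree, sampled without replacement
#'   (default `round(sqrt(n_snps))`).
#' @param burnin trees used to pick the tree depth (default 50).
#' @param depth_grid candidate depths for the burn-in (default 2:6).
#' @param seed master seed; per-tree streams are derived from it so results
#'   do not depend on execution order.
#' @return Object of class `tamw_fit`: `trees`, `tree_depth` (chosen),
#'   `burnin_oob_u` (per candidate depth), `lr_assem` (assembled OOB score,
#'   `NA` for never-OOB subjects), `oob_count` (T_i), `result` (MWU of the
#'   assembled score), `selection_freq` (per-SNP fraction of trees using
#'   the SNP).
#' @export
tamw <- function(gm, ph, n_trees = 500L, mtry = NULL, burnin = 50L,
                 depth_grid = 2:6, min_group_size = 10L, hz = FALSE,
                 smoothing = 0.5, seed = NULL) {
  g <- as_geno_int(gm)
  n <- nrow(g)
  p <- ncol(g)
  snp_ids <- colnames(g) %||% paste0("SNP", seq_len(p))
  mtry <- as.integer(mtry %||% max(1L, round(sqrt(p))))
  if (mtry < 1L || mtry > p)
    stop(new_error("treemwu_format_error",
                   sprintf("mtry must be in [1, %d]", p)))
  burnin <- min(as.integer(burnin), as.integer(n_trees))
  stopifnot(n_trees >= 1L, burnin >= 1L, length(depth_grid) >= 1L)
  depth_grid <- sort(unique(as.integer(depth_grid)))
  max_grid <- max(depth_grid)
  if (!is.null(seed)) set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, n_trees)

  grow_one <- function(t, depth) {
    set.seed(tree_seeds[t])
    repeat {
      boot <- sample.int(n, n, replace = TRUE)
      st <- ph$status[boot]
      if (sum(st) >= 1L && sum(1L - st) >= 1L) break
    }
    snps <- sort(sample.int(p, mtry))
    tr <- tryCatch(
      grow_tree(g, ph, candidate_snps = snps, max_depth = depth,
                min_group_size = min_group_size, hz = hz,
                smoothing = smoothing, subjects = boot),
      treemwu_empty_tree = function(e) NULL)   # root tree: LR 1 everywhere
    list(tree = tr, oob = which(tabulate(boot, n) == 0L), inbag = boot)
  }
  oob_lr <- function(fit, depth) {
    if (is.null(fit$tree)) return(rep(1, length(fit$oob)))
    assign_lr(fit$tree, g, subjects = fit$oob,
              depth = min(depth, fit$tree$depth))$lr
  }

  # Burn-in: grow at the deepest candidate depth; depth-d prefixes are the
  # depth-d trees (forward selection nests), so each candidate depth is
  # scored from the same trees.
  fits <- vector("list", n_trees)
  nd_grid <- length(depth_grid)
  sums <- matrix(0, n, nd_grid)
  cnts <- matrix(0L, n, nd_grid)
  for (t in seq_len(burnin)) {
    fits[[t]] <- grow_one(t, max_grid)
    for (k in seq_len(nd_grid)) {
      lr <- oob_lr(fits[[t]], depth_grid[k])
      sums[fits[[t]]$oob, k] <- sums[fits[[t]]$oob, k] + lr
      cnts[fits[[t]]$oob, k] <- cnts[fits[[t]]$oob, k] + 1L
    }
  }
  burn_u <- vapply(seq_len(nd_grid), function(k) {
    got <- cnts[, k] > 0L
    if (sum(ph$status[got]) < 1L || sum(1L - ph$status[got]) < 1L)
      return(0.5)
    mwu(sums[got, k] / cnts[got, k], ph$status[got])$U
  }, numeric(1))
  names(burn_u) <- depth_grid
  tree_depth <- depth_grid[which.max(burn_u)]   # ties toward shallower
  k_sel <- match(tree_depth, depth_grid)

  # Main phase at the fixed depth; burn-in trees contribute their
  # depth-truncated OOB assignments already accumulated above.
  lr_sum <- sums[, k_sel]
  lr_cnt <- cnts[, k_sel]
  if (n_trees > burnin) {
    for (t in seq(burnin + 1L, n_trees)) {
      fits[[t]] <- grow_one(t, tree_depth)
      lr <- oob_lr(fits[[t]], tree_depth)
      lr_sum[fits[[t]]$oob] <- lr_sum[fits[[t]]$oob] + lr
      lr_cnt[fits[[t]]$oob] <- lr_cnt[fits[[t]]$oob] + 1L
    }
  }
  lr_assem <- ifelse(lr_cnt > 0L, lr_sum / lr_cnt, NA_real_)
  if (any(lr_cnt == 0L))
    warning(sprintf("%d subject(s) never out-of-bag; excluded from the test",
                    sum(lr_cnt == 0L)))

  used <- unlist(lapply(fits, function(f)
    if (is.null(f$tree)) character(0)
    else f$tree$snp_ids[seq_len(min(tree_depth, f$tree$depth))]))
  freq <- table(factor(used, levels = snp_ids)) / n_trees

  structure(list(
    trees = lapply(fits, `[[`, "tree"),
    inbag = lapply(fits, `[[`, "inbag"),
    oob = lapply(fits, `[[`, "oob"),
    n_trees = as.integer(n_trees), mtry = mtry, burnin = burnin,
    depth_grid = depth_grid, tree_depth = as.integer(tree_depth),
    burnin_oob_u = burn_u,
    lr_assem = lr_assem, oob_count = lr_cnt,
    result = mwu(lr_assem, ph$status),
    selection_freq = freq,
    snp_ids = snp_ids,
    params = list(min_group_size = min_group_size, hz = hz,
                  smoothing = smoothing, seed = seed)
  ), class = "tamw_fit")
}

#' Score subjects with a TAMW ensemble
#'
#' External subjects are scored by the mean LR over all trees in the
#' ensemble (no OOB restriction), each tree truncated at the ensemble
#' depth.
#'
#' @param model a [tamw()] fit.
#' @param gm genotype data for the subjects to score.
#' @param subjects optional subject selection.
#' @return An `lr_assignment` whose `lr` is the per-subject ensemble mean.
#' @export
tamw_score <- function(model, gm, subjects = NULL) {
  stopifnot(inherits(model, "tamw_fit"))
  if (!length(model$trees))
    stop(new_error("treemwu_format_error", "empty ensemble"))
  g <- as_geno_int(gm)
  if (!is.null(subjects)) g <- g[as.integer(subjects), , drop = FALSE]
  total <- rep(0, nrow(g))
  for (tr in model$trees) {
    total <- total + if (is.null(tr)) 1 else
      assign_lr(tr, g, depth = min(model$tree_depth, tr$depth))$lr
  }
  structure(list(lr = total / length(model$trees), group = NULL,
                 flagged = NULL, depth = model$tree_depth),
            class = "lr_assignment")
}

#' @export
print.tamw_fit <- function(x, ...) {
  cat(sprintf("TAMW fit: %d trees, mtry = %d, depth %d (burn-in of %d over {%s})\n",
              x$n_trees, x$mtry, x$tree_depth, x$burnin,
              paste(x$depth_grid, collapse = ",")))
  cat(sprintf("OOB assembled AUC = %.4f, p (%s-sided) = %.3g\n",
              x$result$U, x$result$sided, x$result$p_value))
  top <- sort(x$selection_freq[x$selection_freq > 0], decreasing = TRUE)
  cat("Top SNPs by selection frequency:",
      paste(sprintf("%s (%.2f)", names(head(top, 5L)), head(top, 5L)),
            collapse = ", "), "\n")
  invisible(x)
}
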