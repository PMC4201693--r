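# LRMW: forward-selection risk-group tree over all SNPs, with the tree
# depth (number of SNPs, hence number of risk groups) chosen by stratified
# 10-fold cross-validation on the held-out MWU.

#' Stratified cross-validation plan
#'
#' Assigns subjects to folds, stratified by case-control status so every
#' fold keeps roughly the sample's case/control ratio; fold sizes differ by
#' at most one within each stratum.
#'
#' @param ph a [phenotype()].
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the shuffle (optional).
#' @return Object of class `cv_plan` with `fold` (fold index per subject),
#'   `n_folds`, `seed`.
#' @export
make_cv_plan <- function(ph, n_folds = 10L, seed = NULL) {
  stopifnot(inherits(ph, "phenotype"), n_folds >= 2L)
  if (length(ph$status) < n_folds)
    stop(new_error("treemwu_stratification_error",
                   "fewer subjects than folds"))
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(ph$status))
  for (s in 0:1) {
    idx <- which(ph$status == s)
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  for (f in seq_len(n_folds)) {
    st <- ph$status[fold == f]
    if (sum(st) < 1L || sum(1L - st) < 1L)
      stop(new_error("treemwu_stratification_error",
                     sprintf("fold %d has no %s; use fewer folds", f,
                             if (sum(st) < 1L) "cases" else "controls")))
  }
  structure(list(fold = fold, n_folds = as.integer(n_folds), seed = seed),
            class = "cv_plan")
}

#' Fit the LRMW model
#'
#' Grows a depth-`max_depth` forward-selection tree on each fold's training
#' nine tenths, records the validation MWU of every depth prefix on the
#' held-out tenth, averages the validation U per depth across folds, picks
#' the depth with the highest mean (ties toward the shallower tree), and
#' refits a tree of that depth on all data.  The returned `result` is the
#' MWU of the full-data assignment and is training-optimistic; honest
#' p-values come from [split_evaluate()] or [permutation_test()].
#'
#' @inheritParams grow_tree
#' @param max_depth largest depth considered (default 10).
#' @param n_folds cross-validation folds (default 10).
#' @param seed RNG seed controlling the fold shuffle.
#' @param cv_plan optional pre-built [make_cv_plan()] (overrides `n_folds`
#'   and `seed`).
#' @return Object of class `lrmw_fit`: `final_tree`, `optimal_depth`,
#'   `cv_curve` (mean validation U per depth), `cv_fold_u` (fold x depth
#'   matrix), `result` (training MWU), `selected_snps`.
#' @export
lrmw <- function(gm, ph, max_depth = 10L, n_folds = 10L, hz = FALSE,
                 min_group_size = 10L, smoothing = 0.5, seed = NULL,
                 cv_plan = NULL) {
  g <- as_geno_int(gm)
  stopifnot(max_depth >= 1L)
  plan <- cv_plan %||% make_cv_plan(ph, n_folds, seed)
  n_folds <- plan$n_folds

  fold_u <- matrix(NA_real_, n_folds, max_depth)
  for (f in seq_len(n_folds)) {
    train <- which(plan$fold != f)
    val <- which(plan$fold == f)
    tr <- tryCatch(
      grow_tree(g, ph, max_depth = max_depth,
                min_group_size = min_group_size, hz = hz,
                smoothing = smoothing, subjects = train),
      treemwu_empty_tree = function(e) NULL)
    if (is.null(tr)) {                       # root model: no information
      fold_u[f, ] <- 0.5
      next
    }
    for (d in seq_len(max_depth)) {
      a <- assign_lr(tr, g, subjects = val, depth = min(d, tr$depth))
      fold_u[f, d] <- mwu(a$lr, ph$status[val])$U
    }
  }
  cv_curve <- colMeans(fold_u)
  optimal_depth <- which.max(cv_curve)       # first max: ties go shallow

  final_tree <- grow_tree(g, ph, max_depth = optimal_depth,
                          min_group_size = min_group_size, hz = hz,
                          smoothing = smoothing)
  full <- assign_lr(final_tree, g)
  structure(list(
    final_tree = final_tree,
    optimal_depth = as.integer(optimal_depth),
    cv_curve = cv_curve,
    cv_fold_u = fold_u,
    cv_plan = plan,
    result = mwu(full$lr, ph$status),
    selected_snps = final_tree$snp_ids,
    params = list(max_depth = max_depth, n_folds = n_folds, hz = hz,
                  min_group_size = min_group_size, smoothing = smoothing,
                  seed = seed)
  ), class = "lrmw_fit")
}

#' @export
print.lrmw_fit <- function(x, ...) {
  cat(sprintf("LRMW fit: optimal depth %d (CV mean validation U = %.4f)\n",
              x$optimal_depth, x$cv_curve[x$optimal_depth]))
  cat("Selected SNPs:", paste(x$selected_snps, collapse = ", "), "\n")
  cat(sprintf("Training AUC = %.4f (optimistic; use split_evaluate or permutation_test for significance)\n",
              x$result$U))
  invisible(x)
}
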