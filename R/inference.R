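# Honest significance around model selection: permutation of the full
# selection pipeline, and train/test-split evaluation where the model is
# built on training subjects and the MWU p-value is computed on held-out
# subjects only.

extract_u <- function(fit) {
  if (inherits(fit, "mwu_result")) return(fit$U)
  if (is.list(fit) && inherits(fit$result, "mwu_result")) return(fit$result$U)
  if (is.numeric(fit) && length(fit) == 1L) return(as.numeric(fit))
  stop(new_error("treemwu_format_error",
                 "fit procedure must return an mwu_result, a fit with $result, or a number"))
}

#' Permutation test of a full selection pipeline
#'
#' Refits the entire pipeline (including depth selection or burn-in) on
#' each phenotype permutation; skipping the refit makes the p-value
#' anti-conservative.  Uses the add-one estimate
#' `p = (1 + #\{perm U >= observed U\}) / (1 + n_perm)`.
#'
#' @param fit_procedure `function(gm, ph)` running the full pipeline and
#'   returning an object with an MWU result (e.g. a wrapper around [lrmw()]
#'   or [tamw()]).
#' @param gm,ph genotype data and phenotype.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return Object of class `permutation_result`: `observed_U`, `perm_U`,
#'   `n_perm`, `p_value`.
#' @export
permutation_test <- function(fit_procedure, gm, ph, n_perm = 99L,
                             seed = NULL) {
  stopifnot(is.function(fit_procedure), n_perm >= 1L)
  g <- as_geno_int(gm)
  observed <- extract_u(fit_procedure(g, ph))
  if (!is.null(seed)) set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(b) sample(ph$status))
  perm_u <- vapply(seq_len(n_perm), function(b) {
    ph_b <- phenotype(perms[[b]])
    tryCatch(extract_u(fit_procedure(g, ph_b)), error = function(e)
      stop(new_error("treemwu_permutation_error",
                     sprintf("permutation %d: %s", b, conditionMessage(e)))))
  }, numeric(1))
  structure(list(observed_U = observed, perm_U = perm_u,
                 n_perm = as.integer(n_perm),
                 p_value = (1 + sum(perm_u >= observed)) / (1 + n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed U = %.4f, p = %.4g (%d permutations)\n",
              x$observed_U, x$p_value, x$n_perm))
  invisible(x)
}

#' Stratified train/test split indices
#'
#' @param ph a [phenotype()].
#' @param train_fraction fraction of each stratum assigned to training.
#' @param seed RNG seed.
#' @return `list(train, test)` of subject indices.
#' @export
stratified_split <- function(ph, train_fraction = 0.5, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  train <- integer(0)
  for (s in 0:1) {
    idx <- sample(which(ph$status == s))
    k <- round(train_fraction * length(idx))
    if (k < 1L || k >= length(idx))
      stop(new_error("treemwu_stratification_error",
                     "split leaves a half without cases or controls"))
    train <- c(train, idx[seq_len(k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(length(ph$status)), train))
}

#' Score held-out subjects with a fitted model
#'
#' @param fit an `lrmw_fit`, `tamw_fit` or `risk_group_tree`.
#' @param gm genotype data for the subjects to score.
#' @param subjects optional subject selection.
#' @return An `lr_assignment`.
#' @export
score_subjects <- function(fit, gm, subjects = NULL) UseMethod("score_subjects")

#' @export
score_subjects.lrmw_fit <- function(fit, gm, subjects = NULL)
  assign_lr(fit$final_tree, gm, subjects = subjects)

#' @export
score_subjects.tamw_fit <- function(fit, gm, subjects = NULL)
  tamw_score(fit, gm, subjects = subjects)

#' @export
score_subjects.risk_group_tree <- function(fit, gm, subjects = NULL)
  assign_lr(fit, gm, subjects = subjects)

#' Train/test-split evaluation
#'
#' Fits the pipeline on a stratified training subset and computes the MWU
#' (with its normal-approximation p-value) on the held-out subjects only.
#' Because no selection touches the test half, the test p-value is honest.
#'
#' @inheritParams permutation_test
#' @param fit_procedure `function(gm, ph)` returning an `lrmw_fit`,
#'   `tamw_fit` or `risk_group_tree` (anything with a [score_subjects()]
#'   method).
#' @param train_fraction fraction of each stratum used for training
#'   (default 0.5).
#' @param sided sidedness of the test p-value.
#' @return Object of class `split_evaluation`: `fit`, `test_result`
#'   (an `mwu_result`), `train`, `test`, `train_fraction`.
#' @export
split_evaluate <- function(fit_procedure, gm, ph, train_fraction = 0.5,
                           seed = NULL, sided = c("one", "two")) {
  sided <- match.arg(sided)
  g <- as_geno_int(gm)
  sp <- stratified_split(ph, train_fraction, seed)
  gtr <- g[sp$train, , drop = FALSE]
  ph_tr <- phenotype(ph$status[sp$train])
  fit <- fit_procedure(gtr, ph_tr)
  a <- score_subjects(fit, g, subjects = sp$test)
  structure(list(fit = fit,
                 test_result = mwu(a$lr, ph$status[sp$test], sided = sided),
                 train = sp$train, test = sp$test,
                 train_fraction = train_fraction),
            class = "split_evaluation")
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf("train/test evaluation (train fraction %.2f):\n",
              x$train_fraction))
  cat("  test "); print(x$test_result)
  invisible(x)
}

#' Marginal contribution of selected SNPs
#'
#' For an LRMW fit: each selected SNP's single-SNP U (best partition alone)
#' and the increment in training U at the level where the SNP entered
#' (increments telescope to `U(depth) - U(root)`).  For a TAMW fit: each
#' SNP's selection frequency across trees, plus the single-SNP U of the
#' most-selected SNPs.
#'
#' @param fit an `lrmw_fit` or `tamw_fit`.
#' @param gm,ph the data the model was fitted to.
#' @param top for TAMW, how many top-frequency SNPs to report (default 20).
#' @return A data frame; see Details.
#' @export
marginal_contribution <- function(fit, gm, ph, top = 20L)
  UseMethod("marginal_contribution")

single_snp_u <- function(g, ph, snp, hz, smoothing) {
  tr <- tryCatch(
    grow_tree(g, ph, candidate_snps = snp, max_depth = 1L,
              min_group_size = 1L, hz = hz, smoothing = smoothing),
    treemwu_empty_tree = function(e) NULL)
  if (is.null(tr)) 0.5 else tr$u_path[1L]
}

#' @export
marginal_contribution.lrmw_fit <- function(fit, gm, ph, top = 20L) {
  g <- as_geno_int(gm)
  tree <- fit$final_tree
  u1 <- vapply(tree$snp_index, function(j)
    single_snp_u(g, ph, j, tree$hz, tree$smoothing), numeric(1))
  data.frame(snp = tree$snp_ids,
             level = seq_len(tree$depth),
             single_snp_u = u1,
             increment = diff(c(tree$u_root, tree$u_path)))
}

#' @export
marginal_contribution.tamw_fit <- function(fit, gm, ph, top = 20L) {
  g <- as_geno_int(gm)
  freq <- sort(fit$selection_freq[fit$selection_freq > 0], decreasing = TRUE)
  freq <- head(freq, top)
  j <- match(names(freq), fit$snp_ids)
  u1 <- vapply(j, function(jj)
    single_snp_u(g, ph, jj, fit$params$hz, fit$params$smoothing), numeric(1))
  data.frame(snp = names(freq), selection_freq = as.numeric(freq),
             single_snp_u = u1, row.names = NULL)
}
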