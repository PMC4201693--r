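# Mann-Whitney U on likelihood-ratio risk scores.
#
# U = (1 / (N_D * N_Dbar)) * sum_i sum_j psi(LR_i, LR_j), where psi is
# 1 / 0.5 / 0 for a case LR greater / equal / less than a control LR.  U is
# identically the AUC of the LR score.  The variance is the two-sample
# component (jackknife-style) form built from per-subject placements, and
# Z = (U - 0.5) / sqrt(Var(U)) is standard normal under the null.

#' Likelihood ratio of a risk group
#'
#' `P(G|case) / P(G|control)` for a risk group, optionally with additive
#' (Haldane-Anscombe style) smoothing:
#' `((n_cases + s) / (N_D + 2s)) / ((n_controls + s) / (N_Dbar + 2s))`.
#' With `smoothing = 0` this is the plug-in ratio, undefined for
#' zero-control groups (an error).
#'
#' @param n_cases,n_controls counts of cases and controls in the group.
#' @param totals a [phenotype()] or a numeric vector `c(n_case, n_control)`
#'   with the sample totals.
#' @param smoothing nonnegative additive smoothing constant (default 0.5).
#' @return The likelihood ratio, a nonnegative number.
#' @examples
#' likelihood_ratio(10, 5, c(100, 100), smoothing = 0)  # 2
#' @export
likelihood_ratio <- function(n_cases, n_controls, totals, smoothing = 0.5) {
  if (inherits(totals, "phenotype")) totals <- c(totals$n_case, totals$n_control)
  nd <- totals[[1L]]
  nk <- totals[[2L]]
  stopifnot(nd > 0, nk > 0, smoothing >= 0,
            n_cases >= 0, n_controls >= 0)
  if (smoothing == 0 && any(n_controls == 0))
    stop(new_error("treemwu_infinite_lr",
                   "zero-control group with smoothing = 0 gives an infinite LR; use smoothing > 0 or merge groups"))
  ((n_cases + smoothing) / (nd + 2 * smoothing)) /
    ((n_controls + smoothing) / (nk + 2 * smoothing))
}

# Placements: for each x, the fraction of `ref` values strictly below plus
# half the ties.  O(n log n) via sorted reference and findInterval.
placements <- function(x, ref) {
  s <- sort(ref)
  leq <- findInterval(x, s)
  lt <- findInterval(x, s, left.open = TRUE)
  (lt + 0.5 * (leq - lt)) / length(ref)
}

#' Mann-Whitney U test of a likelihood-ratio assignment
#'
#' Computes the normalized U statistic (equal to the AUC of the scores),
#' its variance, the Z statistic and a normal-approximation p-value.
#' Implemented with average ranks in `O(n log n)`; ties contribute 1/2 per
#' the kernel.  Subjects with `NA` scores (never scored) are excluded.
#'
#' @param lr numeric risk scores (likelihood ratios); `NA` allowed.
#' @param status case-control labels: a [phenotype()] or a 0/1 vector
#'   aligned with `lr`.
#' @param sided `"one"` (upper tail, default: scores are built to rank cases
#'   above controls) or `"two"`.
#' @return Object of class `mwu_result`: fields `U`, `var_U`, `Z`,
#'   `p_value`, `auc` (identical to `U`), `n_case`, `n_control`,
#'   `degenerate`.  When `var_U` is 0 the statistic is degenerate: `Z` is
#'   `NA` and `p_value` is 1.
#' @examples
#' mwu(c(2, 3, 1, 2), c(1, 1, 0, 0))$U  # 0.875
#' @export
mwu <- function(lr, status, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(status, "phenotype")) status <- status$status
  stopifnot(length(lr) == length(status))
  ok <- !is.na(lr)
  lr <- lr[ok]
  status <- as.integer(status[ok])
  if (any(!status %in% 0:1))
    stop(new_error("treemwu_phenotype_error", "status must be 0/1"))
  nd <- sum(status == 1L)
  nk <- sum(status == 0L)
  if (nd < 1L || nk < 1L)
    stop(new_error("treemwu_phenotype_error",
                   "need at least one scored case and one scored control"))
  if (any(lr < 0, na.rm = TRUE))
    stop(new_error("treemwu_format_error", "LR scores must be nonnegative"))

  case_lr <- lr[status == 1L]
  ctrl_lr <- lr[status == 0L]
  r <- rank(lr)                                  # average ranks handle ties
  u <- (sum(r[status == 1L]) - nd * (nd + 1) / 2) / (nd * nk)

  p_i <- placements(case_lr, ctrl_lr)            # mean(p_i) == U
  q_j <- 1 - placements(ctrl_lr, case_lr)        # fraction of cases above j
  var_u <- sum((p_i - u)^2) / (nd * (nd - 1)) +
    sum((q_j - u)^2) / (nk * (nk - 1))
  if (nd == 1L || nk == 1L) var_u <- NaN         # component form needs n >= 2

  degenerate <- is.finite(var_u) && var_u <= 0
  z <- if (isTRUE(var_u > 0)) (u - 0.5) / sqrt(var_u) else NA_real_
  p <- if (degenerate) 1 else normal_p(z, sided)
  structure(list(U = u, var_U = var_u, Z = z, p_value = p, auc = u,
                 sided = sided, n_case = nd, n_control = nk,
                 degenerate = degenerate),
            class = "mwu_result")
}

normal_p <- function(z, sided) {
  if (is.na(z)) return(NA_real_)
  if (sided == "one") pnorm(z, lower.tail = FALSE)
  else 2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Normal-approximation p-value of an MWU result
#'
#' @param result an `mwu_result`.
#' @param sided `"one"` or `"two"`.
#' @return The standard-normal tail probability of `Z`; 1 (with the
#'   degenerate flag preserved) when `var_U` is 0.
#' @export
mwu_pvalue <- function(result, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(inherits(result, "mwu_result"))
  if (result$degenerate) return(1)
  normal_p(result$Z, sided)
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("MWU: AUC = %.4f, Z = %s, p (%s-sided) = %.3g%s\n",
              x$U, ifelse(is.na(x$Z), "NA", sprintf("%.3f", x$Z)), x$sided,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
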