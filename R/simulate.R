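# Retrospective case-control genotype simulator.
#
# Genotypes are drawn at Hardy-Weinberg proportions and linkage
# equilibrium; disease status follows a penetrance model, and case/control
# genotype distributions are obtained by Bayes' rule (exactly for the
# enumerable models, by prospective rejection sampling for the many-weak
# polygenic model).  The oracle AUC of the true risk score is computed from
# the discrete distribution of the score.

#' Specify a case-control simulation
#'
#' @param n_cases,n_controls sample sizes.
#' @param n_snps total number of SNPs (causal + null).
#' @param model disease architecture: `"null"` (phenotype independent of
#'   all genotypes), `"marginal"` (one causal SNP), `"epistatic_pair"` (two
#'   interacting SNPs with weak marginals and a strong joint effect),
#'   `"many_weak"` (many causal SNPs with small multiplicative odds
#'   ratios).
#' @param maf_range minor-allele-frequency range for null SNPs, drawn
#'   uniformly.
#' @param effect_params model-specific list; defaults (see Details):
#'   `marginal`: `maf = 0.3`, dominant penetrances `f0 = 0.05`,
#'   `f1 = 0.15`; `epistatic_pair`: `maf = 0.25`, `prevalence = 0.1`,
#'   `oracle_auc = 0.75` (penetrances solved so that carrying a minor
#'   allele at both loci multiplies risk, hitting the requested oracle
#'   AUC); `many_weak`: `n_causal = 50`, per-allele odds ratios drawn
#'   uniformly from `or_range = c(1.1, 1.2)`, `prevalence = 0.1`.
#' @param missing_rate independent genotype missingness rate.
#' @param seed RNG seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_cases, n_controls, n_snps,
                     model = c("null", "marginal", "epistatic_pair",
                               "many_weak"),
                     maf_range = c(0.05, 0.5), effect_params = list(),
                     missing_rate = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  defaults <- switch(model,
    null = list(),
    marginal = list(maf = 0.3, f = c(0.05, 0.15, 0.15)),
    epistatic_pair = list(maf = 0.25, prevalence = 0.1, oracle_auc = 0.75),
    many_weak = list(n_causal = 50L, or_range = c(1.1, 1.2),
                     prevalence = 0.1))
  ep <- utils::modifyList(defaults, effect_params)
  if (model == "epistatic_pair" && is.null(ep$penetrance))
    ep$penetrance <- solve_pair_penetrance(ep$prevalence, ep$maf,
                                           ep$oracle_auc)
  if (model == "many_weak" && ep$n_causal >= n_snps)
    stop(new_error("treemwu_sim_error", "n_causal must be below n_snps"))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_snps = n_snps, model = model, maf_range = maf_range,
                 effect_params = ep, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_spec")
}

# Penetrances for the epistatic pair: the high-risk class is "minor-allele
# carrier at both loci" (probability q = (1 - (1-maf)^2)^2).  With
# a = P(high | case), b = P(high | control), the two-class oracle AUC is
# 0.5 + (a - b)/2, so the target AUC fixes f1 via
# a - b = q * (f1/K - (1 - f1)/(1 - K)), and f0 follows from the prevalence.
solve_pair_penetrance <- function(prevalence, maf, oracle_auc) {
  k <- prevalence
  q <- (1 - (1 - maf)^2)^2
  delta <- 2 * (oracle_auc - 0.5)
  f1 <- (delta / q + 1 / (1 - k)) / (1 / k + 1 / (1 - k))
  f0 <- (k - q * f1) / (1 - q)
  if (any(c(f0, f1) < 0) || any(c(f0, f1) > 1))
    stop(new_error("treemwu_sim_error",
                   "unattainable effect parameters: penetrance outside [0, 1]"))
  list(f_high = f1, f_low = f0, q_high = q)
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# Exact AUC of a discrete score: classes with probabilities under case and
# control and a score value per class; ties contribute 1/2.
auc_discrete <- function(score, p_case, p_ctrl) {
  o <- order(score)
  score <- score[o]
  p_case <- p_case[o]
  p_ctrl <- p_ctrl[o]
  grp <- cumsum(!duplicated(score))
  ca <- tapply(p_case, grp, sum)
  co <- tapply(p_ctrl, grp, sum)
  below <- cumsum(c(0, head(co, -1)))
  sum(ca * (below + 0.5 * co))
}

#' Simulate case-control genotype data
#'
#' @param spec a [sim_spec()].
#' @return `list(genotypes, phenotype, truth)` where `truth` holds the
#'   causal SNP ids, the oracle AUC of the true risk score, the drawn MAFs
#'   and the effect parameters.  Cases come first in the subject order.
#' @export
simulate_cc <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nd <- spec$n_cases
  nk <- spec$n_controls
  n <- nd + nk
  p <- spec$n_snps
  ep <- spec$effect_params

  mafs <- runif(p, spec$maf_range[1], spec$maf_range[2])
  g <- matrix(NA_integer_, n, p)
  causal <- integer(0)
  oracle <- 0.5

  if (spec$model == "null") {
    for (j in seq_len(p)) g[, j] <- rbinom(n, 2L, mafs[j])
  } else if (spec$model == "marginal") {
    causal <- 1L
    mafs[1L] <- ep$maf
    w <- hwe_probs(ep$maf)
    f <- ep$f
    k <- sum(w * f)
    p_case <- w * f / k
    p_ctrl <- w * (1 - f) / (1 - k)
    g[, 1L] <- c(sample(0:2, nd, TRUE, p_case), sample(0:2, nk, TRUE, p_ctrl))
    oracle <- auc_discrete(f / (1 - f), p_case, p_ctrl)
    for (j in seq_len(p)[-1L]) g[, j] <- rbinom(n, 2L, mafs[j])
  } else if (spec$model == "epistatic_pair") {
    causal <- 1:2
    mafs[1:2] <- ep$maf
    w1 <- hwe_probs(ep$maf)
    cls <- expand.grid(gA = 0:2, gB = 0:2)
    w <- w1[cls$gA + 1L] * w1[cls$gB + 1L]
    f <- ifelse(cls$gA >= 1L & cls$gB >= 1L, ep$penetrance$f_high,
                ep$penetrance$f_low)
    k <- sum(w * f)
    p_case <- w * f / k
    p_ctrl <- w * (1 - f) / (1 - k)
    ic <- c(sample(seq_len(9L), nd, TRUE, p_case),
            sample(seq_len(9L), nk, TRUE, p_ctrl))
    g[, 1L] <- cls$gA[ic]
    g[, 2L] <- cls$gB[ic]
    oracle <- auc_discrete(f / (1 - f), p_case, p_ctrl)
    for (j in seq_len(p)[-(1:2)]) g[, j] <- rbinom(n, 2L, mafs[j])
  } else {                                   # many_weak
    nc <- ep$n_causal
    causal <- seq_len(nc)
    beta <- log(runif(nc, ep$or_range[1], ep$or_range[2]))
    cm <- mafs[causal]
    alpha <- solve_alpha(beta, cm, ep$prevalence)
    got_ca <- 0L
    got_co <- 0L
    gc_ca <- matrix(0L, nd, nc)
    gc_co <- matrix(0L, nk, nc)
    while (got_ca < nd || got_co < nk) {
      b <- 4096L
      gb <- vapply(seq_len(nc), function(j) rbinom(b, 2L, cm[j]),
                   integer(b))
      eta <- as.vector(gb %*% beta)
      y <- rbinom(b, 1L, stats::plogis(alpha + eta))
      ca <- which(y == 1L)
      co <- which(y == 0L)
      if (got_ca < nd && length(ca)) {
        take <- head(ca, nd - got_ca)
        gc_ca[got_ca + seq_along(take), ] <- gb[take, , drop = FALSE]
        got_ca <- got_ca + length(take)
      }
      if (got_co < nk && length(co)) {
        take <- head(co, nk - got_co)
        gc_co[got_co + seq_along(take), ] <- gb[take, , drop = FALSE]
        got_co <- got_co + length(take)
      }
    }
    g[, causal] <- rbind(gc_ca, gc_co)
    for (j in seq_len(p)[-causal]) g[, j] <- rbinom(n, 2L, mafs[j])
    oracle <- oracle_auc_logistic(beta, cm, alpha)
  }

  if (spec$missing_rate > 0)
    g[matrix(rbinom(n * p, 1L, spec$missing_rate) == 1L, n, p)] <- NA_integer_

  status <- c(rep(1L, nd), rep(0L, nk))
  gm <- genotype_matrix(g, snp_ids = paste0("SNP", seq_len(p)),
                        subject_ids = paste0("S", seq_len(n)))
  list(genotypes = gm,
       phenotype = phenotype(status, subject_ids = gm$subject_ids),
       truth = list(causal_snps = gm$snp_ids[causal], oracle_auc = oracle,
                    mafs = mafs, effect_params = ep, model = spec$model))
}

# Distribution of the polygenic score eta = sum g_j * beta_j on a fine grid
# (numeric convolution; near-exact up to the grid step).
eta_distribution <- function(beta, maf, step = 5e-4) {
  width <- sum(2 * beta)
  m <- as.integer(ceiling(width / step)) + 2L
  probs <- numeric(m)
  probs[1L] <- 1
  for (j in seq_along(beta)) {
    w <- hwe_probs(maf[j])
    off <- as.integer(round(c(0, beta[j], 2 * beta[j]) / step))
    nxt <- numeric(m)
    nz <- which(probs > 0)
    for (k in 1:3) nxt[nz + off[k]] <- nxt[nz + off[k]] + probs[nz] * w[k]
    probs <- nxt
  }
  nz <- which(probs > 0)
  list(eta = (nz - 1L) * step, w = probs[nz])
}

solve_alpha <- function(beta, maf, prevalence) {
  d <- eta_distribution(beta, maf)
  uniroot(function(a) sum(d$w * stats::plogis(a + d$eta)) - prevalence,
          c(-30, 10), tol = 1e-10)$root
}

oracle_auc_logistic <- function(beta, maf, alpha) {
  d <- eta_distribution(beta, maf)
  f <- stats::plogis(alpha + d$eta)
  k <- sum(d$w * f)
  auc_discrete(d$eta, d$w * f / k, d$w * (1 - f) / (1 - k))
}
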