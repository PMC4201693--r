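# Independent oracles, kept deliberately naive.

# Brute-force double-sum U and component-form variance over all
# case-control pairs with the 1 / 0.5 / 0 kernel.
mwu_brute <- function(lr, status) {
  ca <- lr[status == 1]
  co <- lr[status == 0]
  psi <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  u <- mean(psi)
  vi <- rowMeans(psi)
  vj <- colMeans(psi)
  var_u <- sum((vi - u)^2) / (length(ca) * (length(ca) - 1)) +
    sum((vj - u)^2) / (length(co) * (length(co) - 1))
  list(U = u, var_U = var_u)
}

# Random LR vector with heavy ties (discrete support) and its labels.
random_lr_case <- function(n, n_levels = max(2L, n %/% 10L)) {
  lr <- sample(round(rexp(n_levels), 3), n, replace = TRUE)
  status <- sample(rep_len(0:1, n))
  list(lr = lr, status = status)
}

# Deterministic genotype matrix builder from per-cell counts:
# `cells` is a data.frame with genotype columns, n_case and n_control.
geno_from_cells <- function(cells) {
  gcols <- setdiff(names(cells), c("n_case", "n_control"))
  g <- NULL
  status <- integer(0)
  for (i in seq_len(nrow(cells))) {
    rep_g <- matrix(unlist(rep(cells[i, gcols], cells$n_case[i] + cells$n_control[i])),
                    ncol = length(gcols), byrow = TRUE)
    g <- rbind(g, rep_g)
    status <- c(status, rep(1L, cells$n_case[i]), rep(0L, cells$n_control[i]))
  }
  colnames(g) <- gcols
  list(gm = genotype_matrix(g, snp_ids = gcols),
       ph = phenotype(status))
}
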