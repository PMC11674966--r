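# Independent brute-force oracles. These are written directly from the
# definitions (hypergeometric enumeration, rank-split enumeration, cell-level
# recounts) and never call the package functions they check.

# two-sided Fisher p by explicit hypergeometric enumeration with the
# point-probability rule
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p over all rank splits (no ties assumed)
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) {
    sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Wilcoxon signed-rank p over all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(as.matrix(signs), 1, function(s) sum(r[s]))
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# brute-force per-case burden recount straight from the matrix cells,
# written independently of call_all_arms / burden_per_case
oracle_burden <- function(calls, gene_arm, universe, num = 2, den = 3) {
  t(vapply(colnames(calls), function(cs) {
    altered <- 0L; evaluable <- 0L
    for (a in universe) {
      v <- calls[gene_arm == a, cs]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      evaluable <- evaluable + 1L
      if (den * sum(v < 0) >= num * length(v) ||
          den * sum(v > 0) >= num * length(v)) {
        altered <- altered + 1L
      }
    }
    c(altered = altered, evaluable = evaluable)
  }, c(altered = 0L, evaluable = 0L)))
}

# random small gene x case call matrix plus its arm map, for oracle checks
random_small_cohort <- function(n_arms = sample(2:5, 1),
                                max_genes = 8, max_cases = 10) {
  universe <- arm_universe()[seq_len(n_arms)]
  gene_arm <- unlist(lapply(universe, function(a) {
    rep(a, sample(max_genes, 1))
  }))
  gene_ids <- sprintf("g%03d", seq_along(gene_arm))
  n_cases <- sample(2:max_cases, 1)
  calls <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L, NA), length(gene_arm) * n_cases,
                         replace = TRUE,
                         prob = c(0.1, 0.2, 0.35, 0.2, 0.1, 0.05)),
                  length(gene_arm), n_cases,
                  dimnames = list(gene_ids, sprintf("c%02d", seq_len(n_cases))))
  map <- build_arm_map(data.frame(gene_id = gene_ids, arm = gene_arm,
                                  stringsAsFactors = FALSE),
                       universe = universe)
  list(calls = calls, gene_arm = gene_arm, universe = universe, map = map)
}
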