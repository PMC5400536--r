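# Shared fixture builders and independent oracles.

make_annotation <- function(sample_ids, group, tissue = "tumor") {
  data.frame(sample_id = sample_ids, group = group, tissue = tissue,
             stringsAsFactors = FALSE)
}

# Random seeded ExpressionMatrix with an even good/poor split.
random_expr <- function(n_genes = 10, n_samples = 6, seed = 1,
                        n_good = ceiling(n_samples / 2),
                        tissue = "tumor") {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  grp <- rep(c("good", "poor"), c(n_good, n_samples - n_good))
  expression_matrix(v, make_annotation(colnames(v), grp, tissue))
}

# Independent Benjamini-Hochberg step-up (reference for fdr_correct).
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- min(running, 1)
  }
  q
}

# Exact exceedance-test p-value by enumerating every n1/n2 label split.
exact_exceedance_p <- function(values, n1) {
  n <- length(values)
  obs <- {
    iv <- compute_reference_interval(values[seq_len(n1)])
    exceedance_score(values[-seq_len(n1)], iv)$score
  }
  splits <- utils::combn(n, n - n1)
  scores <- apply(splits, 2, function(case) {
    iv <- compute_reference_interval(values[-case])
    exceedance_score(values[case], iv)$score
  })
  mean(scores >= obs)
}

# Explicit risk-set log-rank arithmetic (reference for km_logrank):
# at each event time, O - E for group 1 and the hypergeometric variance.
logrank_manual <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}
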