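# Small-scale simulation configs and hand-built objects shared across tests.

small_config <- function(seed = 1L, n_background_probes = 80L, n_snps = 40L,
                         ...) {
  simulation_config(seed = seed, n_background_probes = n_background_probes,
                    n_snps = n_snps, ...)
}

# minimal hand-built sample sheet with balanced covariates
toy_samples <- function(n1 = 15L, n0 = 15L, seed = 1L,
                        cohort = "discovery") {
  set.seed(seed)
  n <- n1 + n0
  cells <- rdirichlet(n, c(Neu = 22, CD4T = 6, CD8T = 3.2, Bcell = 2.4,
                           NK = 2, Mono = 3.2, DC = 0.4, Treg = 0.8))
  data.frame(sample_id = sprintf("T%03d", seq_len(n)),
             cohort = cohort,
             treated = rep(c(1L, 0L), c(n1, n0)),
             age = round(runif(n, 25, 65), 1),
             sex = sample(c("F", "M"), n, TRUE),
             days_since_first_treatment =
               ifelse(rep(c(TRUE, FALSE), c(n1, n0)), 10^runif(n, 1, 3.2), NA),
             stringsAsFactors = FALSE) |> cbind(as.data.frame(cells))
}

# brute-force AUC by exhaustive pair counting (independent oracle)
auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# naive Freeman-Halton oracle: enumerate candidate 2x3 tables cell by cell
fh_naive <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  logp <- function(m) sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) -
    lgamma(N + 1) - sum(lgamma(m + 1))
  p_obs <- logp(tab)
  tot <- 0
  for (a in 0:cs[1]) for (b in 0:cs[2]) for (cc in 0:cs[3]) {
    if (a + b + cc != r[1]) next
    m <- rbind(c(a, b, cc), cs - c(a, b, cc))
    if (any(m < 0)) next
    lp <- logp(m)
    if (lp <= p_obs + 1e-7) tot <- tot + exp(lp)
  }
  min(tot, 1)
}
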