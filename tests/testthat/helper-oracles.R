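# Independent oracles and fixture generators shared across the suite.
# Every oracle is a deliberately naive, literal implementation kept separate
# from the code paths it checks.

# literal term-by-term evaluation of the Beals formula
beals_oracle <- function(occ) {
  n <- nrow(occ); m <- ncol(occ)
  n_k <- colSums(occ)
  n_jk <- crossprod(occ)
  P <- matrix(0, n, m, dimnames = dimnames(occ))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s_i <- sum(occ[i, ]) - occ[i, j]
    if (s_i == 0) next
    acc <- 0
    for (k in seq_len(m)) if (k != j) acc <- acc + n_jk[j, k] * occ[i, k] / n_k[k]
    P[i, j] <- acc / s_i
  }
  P
}

# exhaustive-enumeration upper-tail hypergeometric probability:
# draw x1 of N without replacement, x2 marked; P(overlap >= ov)
hyper_oracle <- function(N, x1, x2, ov) {
  if (x1 == 0) return(as.numeric(ov <= 0))
  draws <- utils::combn(N, x1)
  hits <- apply(draws, 2, function(d) sum(d <= x2) >= ov)
  mean(hits)
}

# exhaustive scan of all candidate thresholds for the best TSS
tss_oracle <- function(pred, obs, grid_size = NULL) {
  cand <- if (is.null(grid_size)) sort(unique(c(0, pred, 1)))
          else seq(0, 1, length.out = grid_size)
  best <- -Inf
  for (t in cand) {
    sens <- sum(pred >= t & obs == 1) / sum(obs == 1)
    spec <- sum(pred < t & obs == 0) / sum(obs == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# major-axis slope from the leading eigenvector of the 2x2 covariance
ma_eigen_oracle <- function(x, y) {
  e <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  v <- e$vectors[, 1]
  v[2] / v[1]
}

# Mann-Whitney AUC of a score separating positive from negative cells
rank_auc <- function(score, pos, neg) {
  r <- rank(c(score[pos], score[neg]))
  np <- sum(pos); nn <- sum(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# random binary site x species matrix with named dims and no empty species
random_occ <- function(n_site, n_sp, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_site * n_sp, 1, p), n_site, n_sp,
                dimnames = list(paste0("s", seq_len(n_site)),
                                paste0("sp", seq_len(n_sp))))
    if (all(colSums(m) >= 1)) return(m)
  }
}

# the 4-site / 3-species worked example: A at {1,2}, B at {2,3}, C at {3,4}
worked_example_occ <- function() {
  occ <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  occ[c(1, 2), "A"] <- 1L
  occ[c(2, 3), "B"] <- 1L
  occ[c(3, 4), "C"] <- 1L
  occ
}

# memoised default-scenario pipeline run shared by the acceptance tests
default_pipeline_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(pipeline_config(seed = 1L))
    cache
  }
})
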