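# Shared fixtures and independent oracles used across the suite.

# The 3x3 dosing-regimen scheme matrix with alternatives
# (increasing dose, increasing interval, delaying infusion).
scheme_matrix <- function(labels = c("dose", "interval", "infusion")) {
  judgment_matrix(list(c(1, 7, 7), c("1/7", 1, "1/2"), c("1/7", 2, 1)),
                  labels = labels)
}

# A perfectly consistent matrix a_ij = w_i / w_j.
consistent_matrix <- function(w, labels = names(w)) {
  n <- length(w)
  A <- outer(w, w, "/")
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  dimnames(A) <- list(labels, labels)
  A
}

# Random reciprocal matrix with upper-triangle cells uniform on the Saaty set.
random_saaty_matrix <- function(n) {
  vals <- c(1 / (9:2), 1:9)
  A <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A[i, j] <- sample(vals, 1)
      A[j, i] <- 1 / A[i, j]
    }
  }
  A
}

# Principal eigenvalue by base R's eigen(): the independent reference for
# power-iteration results.
eigen_lambda <- function(A) {
  max(Re(eigen(A, only.values = TRUE)$values))
}

# Two-sided Fisher p by direct hypergeometric enumeration: sum over the
# conditional support of all tables (given the margins) whose probability
# does not exceed that of the observed table (relative slack 1e-7).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the Mann-Whitney rank statistic: mean over all case-control pairs
# of 1 (case score higher), 1/2 (tie), 0.
auc_rank_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}
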