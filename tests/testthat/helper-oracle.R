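# Independent brute-force centrality oracle used only by tests:
# Floyd-Warshall distances, explicit shortest-path counting for
# betweenness, eigen() for the principal eigenvector. Conventions match
# the package's documented definitions but share no code with them.
bruteCentralities <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  deg <- rowSums(A > 0) / max(1, n - 1)
  clo <- vapply(seq_len(n), function(v) {
    if (n == 1) return(0)
    d <- D[v, -v]
    mean(ifelse(is.finite(d), 1 / d, 0))
  }, 0)
  # shortest-path counts sigma[s, t] by dynamic programming over distance
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    tot
  }, 0)
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  # eigenvector per component (principal eigenvector, max entry 1)
  eig <- numeric(n)
  compId <- rep(NA_integer_, n)
  for (v in seq_len(n)) compId[v] <- min(which(is.finite(D[v, ])))
  for (c0 in unique(compId)) {
    vs <- which(compId == c0)
    if (length(vs) == 1) {
      eig[vs] <- 1
    } else {
      ev <- abs(eigen((A[vs, vs, drop = FALSE] > 0) * 1,
                      symmetric = TRUE)$vectors[, 1])
      eig[vs] <- ev / max(ev)
    }
  }
  data.frame(degree = unname(deg), betweenness = unname(btw),
             closeness = unname(clo), eigenvector = unname(eig))
}
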