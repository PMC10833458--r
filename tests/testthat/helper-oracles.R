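# Independent oracles used to check the package's implementations.
# Each is written as a direct, unoptimized transcription of the definition
# and must stay independent of the code paths it validates.

# exhaustive one-step fit: try every split, keep the first SSE minimum
brute_step <- function(x) {
  n <- length(x)
  all_sse <- vapply(seq_len(n - 1L), function(k) {
    left <- x[1:k]
    right <- x[(k + 1L):n]
    sum((left - mean(left))^2) + sum((right - mean(right))^2)
  }, numeric(1))
  list(k = which.min(all_sse), sse = min(all_sse), all_sse = all_sse)
}

# AUC by exhaustive pair counting: concordant + half ties over all pairs
pair_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg by direct step-up enumeration with monotone cap
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj[i] <- min(adj[i], adj[i + 1])
  }
  pmin(adj, 1)[order(o)]
}

# two-group log-rank by hypergeometric increments at each event time
logrank_oracle <- function(time, event, group) {
  g1 <- unique(group)[1L]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# hypergeometric upper tail by enumerating every possible draw of the hits
hyper_enum <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K) # first K universe elements form the set
  overlaps <- apply(draws, 2L, function(d) sum(d %in% in_set))
  mean(overlaps >= k_obs)
}

# small expression matrix fixture with a named group annotation
toy_matrix <- function(values, groups = NULL) {
  ann <- if (!is.null(groups)) {
    tibble::tibble(sample_id = colnames(values), condition = groups)
  }
  expression_matrix(values, annotations = ann)
}
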