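# Brute-force oracles, independent of the package implementation.

# Spearman rho: explicit average ranks + the Pearson sum formula, by loops.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    # mean position of the tied block in the sorted order
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      lower <- sum(v < v[i])
      ties <- sum(v == v[i])
      r[i] <- lower + (ties + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# AUC by explicit pair enumeration with the 1 / 0.5 / 0 kernel.
oracle_auc <- function(x, y) {
  total <- 0
  for (a in x) for (b in y) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# nearest-anchor classification by exhaustive search over candidate anchors
# (ties resolved to the larger anchor, i.e. the half-open [-160, 160) window)
oracle_classify <- function(onset) {
  q <- onset %/% 960
  res <- onset %% 960
  anchors <- c(0, 320, 640, 960)
  dist <- abs(res - anchors)
  best <- max(which(dist == min(dist)))  # tie -> upper anchor
  anchor <- anchors[best]
  offset <- res - anchor
  if (anchor == 960) { q <- q + 1; anchor <- 0 }
  klass <- c("base", "disregarded", "swing", "base")[best]
  list(quarter = q, klass = klass, anchor = anchor, offset = offset)
}

# analytic AUC for two discretised latent-normal samples: category
# probabilities px, py over ordered categories
oracle_auc_from_probs <- function(px, py) {
  auc <- 0
  for (i in seq_along(px)) {
    below <- if (i > 1) sum(py[1:(i - 1)]) else 0
    auc <- auc + px[i] * (below + 0.5 * py[i])
  }
  auc
}

# discretise a latent normal sample at thresholds into categories 1..k+1
discretise <- function(z, thresholds) {
  findInterval(z, thresholds) + 1L
}
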