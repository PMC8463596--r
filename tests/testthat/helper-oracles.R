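# Brute-force oracles, independent of the package implementations they check.

# AUROC by exhaustive positive x negative pair comparison.
auroc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Average precision by explicit sweep over distinct thresholds.
auprc_sweep_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; prev_tp <- 0
  for (th in thr) {
    called <- scores >= th
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    ap <- ap + (tp - prev_tp) * prec
    prev_tp <- tp
  }
  ap / n_pos
}

# All confusion-matrix rates at every achievable threshold (call >= thr).
sweep_rates_oracle <- function(scores, labels) {
  thr <- c(sort(unique(scores)), Inf)
  do.call(rbind, lapply(thr, function(th) {
    called <- scores >= th
    tp <- sum(called & labels == 1); fp <- sum(called & labels == 0)
    fn <- sum(!called & labels == 1); tn <- sum(!called & labels == 0)
    data.frame(threshold = th,
               sens = ifelse(tp + fn > 0, tp / (tp + fn), NA),
               spec = ifelse(tn + fp > 0, tn / (tn + fp), NA),
               ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA),
               npv = ifelse(tn + fn > 0, tn / (tn + fn), NA),
               biopsy_rate = (tp + fp) / length(labels))
  }))
}

# Top-n mean by explicit sort.
top_t_sort_oracle <- function(map, t) {
  v <- sort(as.vector(map), decreasing = TRUE)
  n <- max(1, ceiling(t * length(v)))
  mean(v[seq_len(n)])
}

# Gated attention by direct per-image evaluation of the printed formula,
# with log-sum-exp stabilization.
gated_attention_oracle <- function(vectors, params) {
  e <- t(vapply(vectors, function(v) {
    g <- tanh(as.vector(params$V %*% v)) * plogis(as.vector(params$U %*% v))
    as.vector(t(params$w) %*% g)
  }, numeric(2)))
  apply(e, 2, function(col) {
    z <- exp(col - max(col))
    z / sum(z)
  })
}

random_prediction_table <- function(n, seed) {
  set.seed(seed)
  repeat {
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) == 2) break
  }
  # mix of ties and unique scores
  scores <- round(runif(n), sample(c(1, 2, 6), 1))
  list(scores = scores, labels = labels)
}
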