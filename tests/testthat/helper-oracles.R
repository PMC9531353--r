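# Independent oracles used across the suite. Each re-derives a quantity
# by a route separate from the package implementation it checks.

# Random DNA sequence over ACGT.
randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force triplet index: position of the triplet in the sorted list
# of all 64 ACGT triplets (lexicographic), built by enumeration rather
# than arithmetic.
bruteTripletIndex <- function(triplet) {
  bases <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(bases, bases, bases), 1, paste,
                      collapse = ""))
  match(triplet, all64)
}

# Brute-force triplet encoding via substring extraction and table lookup.
bruteEncode <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n - 2), function(i) {
    tri <- substr(s, i, i + 2)
    if (grepl("N", tri)) 0L else as.integer(bruteTripletIndex(tri))
  }, integer(1))
}

# Pairwise concordance AUC: fraction of positive-negative pairs ranked
# correctly, with half credit for ties.
concordanceAuc <- function(labels, scores) {
  posScores <- scores[labels == 1]
  negScores <- scores[labels == 0]
  total <- 0
  for (p in posScores) {
    total <- total + sum(p > negScores) + 0.5 * sum(p == negScores)
  }
  total / (length(posScores) * length(negScores))
}

# Brute-force step-rule PR area: explicit threshold sweep, precision
# summed over recall increments.
brutePrArea <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  lastRecall <- 0
  area <- 0
  npos <- sum(labels == 1)
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    recall <- tp / npos
    precision <- tp / sum(called)
    area <- area + (recall - lastRecall) * precision
    lastRecall <- recall
  }
  area
}

# Pure-R reference forward pass of the classifier, mirroring the
# documented layer stack and parameter layout but sharing no code with
# the compiled implementation. Inference mode (running batchnorm stats).
referenceForward <- function(params, X, leakySlope) {
  # vector-valued parameters arrive as 1-column matrices; flatten them
  for (nm in c("bn_gamma", "bn_beta", "bn_run_mean", "bn_run_var",
               "lstm_fwd_b", "lstm_bwd_b", "fc1_b", "fc2_b"))
    params[[nm]] <- as.numeric(params[[nm]])
  E <- params$embedding                     # D x vocab
  D <- nrow(E)
  Tn <- ncol(X)
  H <- ncol(params$lstm_fwd_Wh)
  sig <- function(x) 1 / (1 + exp(-x))
  probs <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    emb <- E[, X[r, ] + 1, drop = FALSE]    # D x T
    xn <- (emb - params$bn_run_mean) / sqrt(params$bn_run_var + 1e-5) *
      params$bn_gamma + params$bn_beta
    runDir <- function(Wx, Wh, b, order) {
      h <- numeric(H); cc <- numeric(H)
      hs <- matrix(0, H, Tn)
      for (t in order) {
        a <- as.numeric(Wx %*% xn[, t] + Wh %*% h + b)
        i <- sig(a[1:H]); f <- sig(a[(H + 1):(2 * H)])
        g <- tanh(a[(2 * H + 1):(3 * H)]); o <- sig(a[(3 * H + 1):(4 * H)])
        cc <- f * cc + i * g
        h <- o * tanh(cc)
        hs[, t] <- h
      }
      hs
    }
    hf <- runDir(params$lstm_fwd_Wx, params$lstm_fwd_Wh, params$lstm_fwd_b,
                 1:Tn)
    hb <- runDir(params$lstm_bwd_Wx, params$lstm_bwd_Wh, params$lstm_bwd_b,
                 Tn:1)
    flat <- as.numeric(rbind(hf, hb))       # t-major, fwd block then bwd
    z1 <- as.numeric(params$fc1_W %*% flat + params$fc1_b)
    a1 <- ifelse(z1 > 0, z1, leakySlope * z1)
    z2 <- as.numeric(params$fc2_W %*% a1 + params$fc2_b)
    probs[r] <- sig(z2)
  }
  probs
}

# Small simulation config used across tests.
testSimConfig <- function(seed = 401L, mutationProb = 0.1,
                          promoterClass = "TATA") {
  SimConfig(promoterClass = promoterClass, mutationProb = mutationProb,
            seed = seed)
}
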