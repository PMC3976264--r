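# Independent oracles used across tests.  Each is a direct, brute-force
# evaluation of the defining formula, kept free of any package internals.

# Step-up FDR: q_(i) = min_{j >= i} p_(j) * m / j, returned in input order.
bh_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(ps)
  q <- vapply(seq_len(k), function(i) {
    min(pmin(1, ps[i:k] * m / (i:k)))
  }, numeric(1))
  out <- numeric(k)
  out[ord] <- q
  out
}

# Mann-Whitney AUC by exhaustive pair enumeration.
auc_paircount <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == -1]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Primal hinge objective of an arbitrary (w, b) on given data.
primal_objective <- function(w, b, X, y, C = 1) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
}

# libsvm (via e1071) as an independent convex-minimization oracle for the
# primal objective: recover its linear decision function by least squares
# on the decision values and evaluate the primal objective there.
libsvm_objective <- function(X, y, C = 1) {
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = C,
                    scale = FALSE, tolerance = 1e-9)
  dv <- drop(attr(predict(fit, X, decision.values = TRUE),
                  "decision.values"))
  coefs <- qr.solve(cbind(X, 1), dv)
  p <- ncol(X)
  # libsvm orients the decision values towards its first training label;
  # evaluate both orientations and keep the one the objective favours
  min(primal_objective(coefs[1:p], coefs[p + 1], X, y, C),
      primal_objective(-coefs[1:p], -coefs[p + 1], X, y, C))
}

# Small replicate-table builder for pre-processing tests.
make_replicates <- function(sample, mir, ct) {
  n <- length(ct)
  data.frame(sample = rep_len(sample, n), mir = rep_len(mir, n),
             replicate = seq_len(n), ct = ct, stringsAsFactors = FALSE)
}

# A ct_table straight from a matrix-like spec.
make_ct <- function(values, ceiling = 34) {
  ct_table(values, ceiling = ceiling)
}
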