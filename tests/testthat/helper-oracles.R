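# Independent brute-force oracles, deliberately written with different
# primitives than the package (explicit sorting / loops, no rank(), no
# p.adjust) so they can serve as cross-checks.

# quantile ranks of one vector via explicit sorting and tie averaging
oracle_qrank <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r / n
}

# scores A and B from an expression matrix and gene sets, loop-based
oracle_scores <- function(m, sets) {
  q <- apply(m, 2, oracle_qrank)
  rownames(q) <- rownames(m)
  out <- data.frame(sample_id = colnames(m), score_A = NA_real_,
                    score_B = NA_real_, stringsAsFactors = FALSE)
  for (s in seq_len(ncol(q))) {
    mq <- sq <- numeric(4)
    nms <- c("iCMS2_up", "iCMS2_down", "iCMS3_up", "iCMS3_down")
    for (k in 1:4) {
      g <- intersect(sets[[nms[k]]], rownames(q))
      v <- q[g, s]
      mq[k] <- sum(v) / length(v)
      sq[k] <- sum(v)
    }
    out$score_A[s] <- mq[1] / mq[2] - mq[3] / mq[4]
    out$score_B[s] <- (sq[1] - sq[2]) - (sq[3] - sq[4])
  }
  out
}

# Benjamini-Hochberg by the definitional step-up procedure
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  pmin(q, 1)
}

# Welch t statistic, df and two-sided p from first principles
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# tiny gene-set fixture shared by several tests
tiny_sets <- function() {
  structure(list(iCMS2_up = c("a", "b"), iCMS2_down = c("c", "d"),
                 iCMS3_up = c("e", "f"), iCMS3_down = c("g", "h")),
            class = "icms_gene_sets")
}

# handcrafted single-sample rank matrix matching the worked scoring example
worked_example_ranks <- function() {
  matrix(c(0.9, 1.0, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7), ncol = 1,
         dimnames = list(letters[1:8], "s1"))
}
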