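# Independent brute-force oracles, written as naive element-wise loops from
# the method definitions.  They deliberately share no code with R/.

# geNorm: M_j = mean over k != j of sd_{n-1}( log2 q_j - log2 q_k ).
oracle_genorm_m <- function(q) {
  genes <- colnames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    vs <- c()
    for (k in setdiff(genes, j)) {
      lr <- c()
      for (i in seq_len(nrow(q))) {
        if (!is.na(q[i, j]) && !is.na(q[i, k])) {
          lr <- c(lr, log2(q[i, j]) - log2(q[i, k]))
        }
      }
      mu <- sum(lr) / length(lr)
      vs <- c(vs, sqrt(sum((lr - mu)^2) / (length(lr) - 1)))
    }
    m[j] <- sum(vs) / length(vs)
  }
  m
}

# geNorm V series from an explicit ranking (best-first gene order).
oracle_v_series <- function(q, ordered_genes) {
  gm <- function(x) exp(sum(log(x)) / length(x))
  nf <- function(n) apply(q[, ordered_genes[1:n], drop = FALSE], 1,
                          function(row) gm(row))
  ns <- 2:(length(ordered_genes) - 1)
  v <- numeric(length(ns))
  for (ii in seq_along(ns)) {
    lr <- log2(nf(ns[ii]) / nf(ns[ii] + 1))
    mu <- mean(lr)
    v[ii] <- sqrt(sum((lr - mu)^2) / (length(lr) - 1))
  }
  v
}

# NormFinder, step by step on x = log2 quantities (rows samples, cols genes).
oracle_normfinder <- function(x, grp) {
  genes <- colnames(x)
  k <- length(genes)
  glev <- unique(grp)
  G <- length(glev)
  ng <- sapply(glev, function(g) sum(grp == g))

  sigma2 <- z <- matrix(0, G, k, dimnames = list(glev, genes))
  for (gi in seq_len(G)) {
    xg <- x[grp == glev[gi], , drop = FALSE]
    n <- nrow(xg)
    grand <- mean(xg)
    r <- matrix(0, n, k)
    for (i in 1:n) for (j in 1:k) {
      r[i, j] <- xg[i, j] - mean(xg[, j]) - mean(xg[i, ]) + grand
    }
    s <- numeric(k)
    for (j in 1:k) s[j] <- sum(r[, j]^2) / (n - 1)
    for (j in 1:k) sigma2[gi, j] <- max(0, k / (k - 2) * (s[j] - mean(s) / (k - 1)))
    for (j in 1:k) z[gi, j] <- mean(xg[, j]) - grand
  }
  zbar <- numeric(k)
  for (j in 1:k) zbar[j] <- sum(ng * z[, j]) / sum(ng)
  d <- sweep(z, 2, zbar)
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(sweep(sigma2, 1, ng, "/")))
  stab <- numeric(k)
  names(stab) <- genes
  for (j in 1:k) {
    acc <- 0
    for (gi in 1:G) {
      son <- sigma2[gi, j] / ng[gi]
      dt <- if (gamma2 + son > 0) d[gi, j] * gamma2 / (gamma2 + son) else 0
      vt <- if (gamma2 + son > 0) gamma2 * son / (gamma2 + son) else 0
      acc <- acc + abs(dt) + sqrt(vt)
    }
    stab[j] <- acc / G
  }
  list(d = d, sigma2 = sigma2, gamma2 = gamma2, stability = stab)
}

# BestKeeper descriptives, direct formulas.
oracle_bestkeeper <- function(cq, variant = "mad") {
  gm <- function(x) exp(mean(log(x)))
  idx <- apply(cq, 1, gm)
  genes <- colnames(cq)
  disp <- r <- numeric(length(genes))
  names(disp) <- names(r) <- genes
  for (j in genes) {
    disp[j] <- if (variant == "mad") mean(abs(cq[, j] - mean(cq[, j]))) else sd(cq[, j])
    r[j] <- suppressWarnings(cor(cq[, j], idx))
  }
  list(index = idx, disp = disp, r = r)
}
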