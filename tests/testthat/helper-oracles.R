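# Independent brute-force oracles, written with naive loops so they share no
# code path with the package implementation.

# nearest-shrunken-centroid quantities, one feature / class at a time
brute_nsc <- function(x, groups, delta, prior = "empirical",
                      mk_variant = "exact") {
  groups <- as.factor(groups)
  classes <- levels(groups)
  n <- ncol(x); K <- length(classes); m <- nrow(x)
  overall <- numeric(m)
  centroids <- matrix(0, m, K)
  s <- numeric(m)
  for (i in seq_len(m)) {
    overall[i] <- mean(x[i, ])
    ss <- 0
    for (k in seq_len(K)) {
      idx <- which(groups == classes[k])
      centroids[i, k] <- mean(x[i, idx])
      for (j in idx) ss <- ss + (x[i, j] - centroids[i, k])^2
    }
    s[i] <- sqrt(ss / (n - K))
  }
  s0 <- stats::median(s)
  mk <- numeric(K); d <- matrix(0, m, K)
  dsh <- matrix(0, m, K); csh <- matrix(0, m, K)
  for (k in seq_len(K)) {
    nk <- sum(groups == classes[k])
    mk[k] <- if (mk_variant == "exact") sqrt(1 / nk - 1 / n)
             else sqrt(1 / nk + 1 / n)
    for (i in seq_len(m)) {
      d[i, k] <- (centroids[i, k] - overall[i]) / (mk[k] * (s[i] + s0))
      dsh[i, k] <- sign(d[i, k]) * max(abs(d[i, k]) - delta, 0)
      csh[i, k] <- overall[i] + mk[k] * (s[i] + s0) * dsh[i, k]
    }
  }
  pri <- if (prior == "empirical")
    as.numeric(table(groups)[classes]) / n else rep(1 / K, K)
  list(overall = overall, centroids = centroids, s = s, s0 = s0,
       mk = mk, d = d, d_shrunk = dsh, centroids_shrunk = csh,
       prior = pri, classes = classes)
}

brute_nsc_predict <- function(bm, xnew) {
  K <- length(bm$classes)
  nn <- ncol(xnew)
  disc <- matrix(0, nn, K)
  for (j in seq_len(nn)) {
    for (k in seq_len(K)) {
      acc <- 0
      for (i in seq_len(nrow(xnew)))
        acc <- acc + (xnew[i, j] - bm$centroids_shrunk[i, k])^2 /
          (bm$s[i] + bm$s0)^2
      disc[j, k] <- acc - 2 * log(bm$prior[k])
    }
  }
  post <- matrix(0, nn, K)
  for (j in seq_len(nn)) {
    e <- exp(-(disc[j, ] - min(disc[j, ])) / 2)
    post[j, ] <- e / sum(e)
  }
  list(class = bm$classes[apply(disc, 1, which.min)], posterior = post)
}

# exact upper-tail hypergeometric p by enumerating all size-n selections
brute_hyper <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  sel <- utils::combn(N, n)
  hits <- apply(sel, 2, function(s) sum(s %in% inset))
  mean(hits >= k)
}

# small random abundance matrix fixture
rand_abundance <- function(n_feat = 10, groups = rep(c("A", "B"), each = 4),
                           omics = "protein", seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_feat * length(groups)), n_feat,
                dimnames = list(sprintf("f%d", 1:n_feat),
                                sprintf("s%d", seq_along(groups))))
  })
  abundance_matrix(x, groups, omics)
}

# tiny two-edge network over explicitly typed nodes
toy_network <- function() {
  signed_network(
    data.frame(node1 = c("miR-a", "P1"), node2 = c("P1", "P2"),
               sign = c(-1L, 1L)),
    c("miR-a" = "mirna", P1 = "protein", P2 = "protein"))
}
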