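# Independent brute-force oracles for the graph measures and the
# statistics, written as plain loops with no shared code with the
# package internals.

random_wgraph <- function(n, density = 0.6) {
  repeat {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < density) W[i, j] <- W[j, i] <- runif(1, 0.05, 1)
    }
    if (sum(W[upper.tri(W)] > 0) >= 2) return(W)
  }
}

oracle_degree_strength <- function(W, threshold = 0) {
  n <- nrow(W)
  deg <- str <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j == i) next
    if (W[i, j] > threshold) deg[i] <- deg[i] + 1
    str[i] <- str[i] + W[i, j]
  }
  list(degree = mean(deg), strength = mean(str))
}

# Floyd-Warshall on inverse-weight connection lengths
oracle_distances <- function(W, lengths = NULL) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0)
      d[i, j] <- if (is.null(lengths)) 1 / W[i, j] else lengths[i, j]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_measures <- function(d) {
  n <- nrow(d)
  ecc <- rep(NA_real_, n)
  cpl_sum <- 0; cpl_n <- 0; eff_sum <- 0; eff_n <- 0
  for (i in seq_len(n)) {
    mx <- NA_real_
    for (j in seq_len(n)) {
      if (i == j) next
      eff_n <- eff_n + 1
      if (is.finite(d[i, j])) {
        cpl_sum <- cpl_sum + d[i, j]; cpl_n <- cpl_n + 1
        eff_sum <- eff_sum + 1 / d[i, j]
        if (is.na(mx) || d[i, j] > mx) mx <- d[i, j]
      }
    }
    ecc[i] <- mx
  }
  list(radius = min(ecc, na.rm = TRUE), diameter = max(ecc, na.rm = TRUE),
       characteristic_path_length = cpl_sum / cpl_n,
       global_efficiency = eff_sum / eff_n)
}

oracle_clustering_transitivity <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  Ci <- numeric(n)
  num_tot <- 0; den_tot <- 0
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    cyc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      if (W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        cyc <- cyc + ((W[i, j] / mx) * (W[i, h] / mx) *
                        (W[j, h] / mx))^(1 / 3)
    }
    num_tot <- num_tot + cyc
    den_tot <- den_tot + k * (k - 1)
    Ci[i] <- if (k >= 2) cyc / (k * (k - 1)) else 0
  }
  list(clustering_coefficient = mean(Ci),
       transitivity = if (den_tot > 0) num_tot / den_tot else 0)
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  eloc <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(W[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- W[nb, nb, drop = FALSE]
    lengths <- matrix(Inf, k, k)
    for (a in seq_len(k)) for (b in seq_len(k))
      if (a != b && sub[a, b] > 0) lengths[a, b] <- (1 / sub[a, b])^(1 / 3)
    dsub <- oracle_distances(sub, lengths = lengths)
    tot <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b || !is.finite(dsub[a, b]) || dsub[a, b] == 0) next
      tot <- tot + (W[u, nb[a]] * W[u, nb[b]])^(1 / 3) / dsub[a, b]
    }
    eloc[u] <- tot / (k * (k - 1))
  }
  mean(eloc)
}

oracle_assortativity <- function(W) {
  n <- nrow(W)
  s <- rowSums(W)
  xs <- ys <- ws <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || W[i, j] == 0) next
    xs <- c(xs, s[i]); ys <- c(ys, s[j]); ws <- c(ws, W[i, j])
  }
  sw <- sum(ws)
  ex <- sum(ws * xs) / sw; ey <- sum(ws * ys) / sw
  vx <- sum(ws * xs^2) / sw - ex^2
  vy <- sum(ws * ys^2) / sw - ey^2
  if (vx <= 1e-15 || vy <= 1e-15) return(0)
  (sum(ws * xs * ys) / sw - ex * ey) / sqrt(vx * vy)
}

oracle_modularity_q <- function(W, memb, gamma = 1) {
  n <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j])
      q <- q + W[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# all set partitions of n items as restricted-growth strings
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_q <- function(W, gamma = 1) {
  parts <- enumerate_partitions(nrow(W))
  m2 <- sum(W)
  k <- rowSums(W)
  B <- W - gamma * outer(k, k) / m2
  best <- -Inf; best_p <- NULL
  for (p in parts) {
    q <- sum(B[outer(p, p, "==")]) / m2
    if (q > best) { best <- q; best_p <- p }
  }
  list(Q = best, partition = best_p)
}

# exhaustive two-sample permutation p (two-sided, mean difference)
oracle_perm_p <- function(x, y) {
  z <- c(x, y)
  nA <- length(x)
  obs <- mean(x) - mean(y)
  cc <- utils::combn(length(z), nA)
  ds <- apply(cc, 2, function(ix) mean(z[ix]) - mean(z[-ix]))
  mean(abs(ds) >= abs(obs) - 1e-12)
}

# Benjamini-Hochberg step-up by direct formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}
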