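# Independent brute-force oracles. These are deliberately written as
# plain, slow loops so they share no code path with the package
# implementation they check.

random_alignment <- function(n, L, n_var = max(2L, L %/% 3L)) {
  # random sequences derived from a common ancestor with sprinkled changes
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  for (i in seq_len(n)) {
    nm <- stats::rpois(1, n_var / 2)
    if (nm > 0) {
      for (s in sample.int(L, min(nm, L))) {
        m[i, s] <- sample(setdiff(c("A", "C", "G", "T"), m[i, s]), 1)
      }
    }
  }
  rownames(m) <- paste0("s", seq_len(n))
  mt_alignment(m)
}

oracle_hamming <- function(a) {
  m <- unclass(a)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0
    for (s in seq_len(ncol(m))) if (m[i, s] != m[j, s]) cnt <- cnt + 1
    d[i, j] <- cnt
  }
  d
}

oracle_pi <- function(a) {
  d <- oracle_hamming(a)
  n <- nrow(d)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + d[i, j]; np <- np + 1
  }
  (tot / np) / ncol(a)
}

oracle_segregating <- function(a) {
  m <- unclass(a)
  s <- 0
  for (j in seq_len(ncol(m))) {
    st <- unique(m[, j])
    st <- st[st %in% c("A", "C", "G", "T")]
    if (length(st) > 1) s <- s + 1
  }
  s
}

oracle_tajima_d <- function(n, S, k_hat) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# unsigned Stirling numbers of the first kind via expansion of the rising
# factorial x(x+1)...(x+n-1); exact in double up to n ~ 15
oracle_stirling1 <- function(n) {
  coefs <- c(0, 1) # x
  if (n >= 2) for (m in 1:(n - 1)) {
    # multiply polynomial by (x + m)
    coefs <- c(0, coefs) + m * c(coefs, 0)
  }
  coefs[2:(n + 1)] # k = 1..n
}

oracle_ewens_pmf <- function(n, theta) {
  s1 <- oracle_stirling1(n)
  denom <- prod(theta + 0:(n - 1))
  s1 * theta^seq_len(n) / denom
}

oracle_fs <- function(n, k0, k_hat) {
  pmf <- oracle_ewens_pmf(n, k_hat)
  sp <- sum(pmf[k0:n])
  log(sp / (1 - sp))
}

# AMOVA sums of squares computed from explicit per-group double loops
oracle_amova <- function(d, pop) {
  groups <- unique(pop)
  N <- length(pop)
  P <- length(groups)
  ssd_wp <- 0
  for (g in groups) {
    ix <- which(pop == g)
    acc <- 0
    for (i in ix) for (j in ix) acc <- acc + d[i, j]
    ssd_wp <- ssd_wp + acc / (2 * length(ix))
  }
  acc <- 0
  for (i in 1:N) for (j in 1:N) acc <- acc + d[i, j]
  ssd_tot <- acc / (2 * N)
  ssd_ap <- ssd_tot - ssd_wp
  s2w <- ssd_wp / (N - P)
  nbar <- (N - sum(table(pop)^2) / N) / (P - 1)
  s2a <- (ssd_ap / (P - 1) - s2w) / nbar
  list(ssd_among = ssd_ap, ssd_within = ssd_wp,
       sigma2_a = s2a, sigma2_w = s2w, fst = s2a / (s2a + s2w))
}

# sudden-expansion mismatch probabilities by direct term-by-term summation
oracle_expected_mismatch <- function(tau, th0, th1, j_max) {
  fhat <- function(theta, j) theta^j / (theta + 1)^(j + 1)
  out <- numeric(j_max + 1)
  for (j in 0:j_max) {
    conv <- 0
    for (i in 0:j) {
      conv <- conv + tau^i / factorial(i) *
        (fhat(th0, j - i) - fhat(th1, j - i))
    }
    out[j + 1] <- fhat(th1, j) + exp(-tau * (th1 + 1) / th1) * conv
  }
  out
}

# an edge belongs to some minimum spanning tree iff its weight equals the
# minimax path weight between its endpoints (bottleneck shortest path)
oracle_msn_edges <- function(seqs) {
  k <- length(seqs)
  sp <- strsplit(seqs, "")
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d[i, j] <- sum(sp[[i]] != sp[[j]])
  }
  mm <- d
  for (via in seq_len(k)) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      mm[i, j] <- min(mm[i, j], max(mm[i, via], mm[via, j]))
    }
  }
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (d[i, j] == mm[i, j]) out <- rbind(out, c(i, j, d[i, j]))
  }
  data.frame(from = out[, 1], to = out[, 2], weight = out[, 3])
}

# exhaustive quasi-median hull: closure of the haplotype set under the
# quasi-median operation applied to every triple
oracle_qm_hull <- function(seqs, max_size = 200) {
  majority_qm <- function(x, y, z) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    cz <- strsplit(z, "")[[1]]
    cols <- list()
    for (j in seq_along(cx)) {
      st <- c(cx[j], cy[j], cz[j])
      tb <- table(st)
      cols[[j]] <- if (max(tb) >= 2) names(tb)[which.max(tb)]
                   else sort(unique(st))
    }
    grid <- expand.grid(cols, stringsAsFactors = FALSE)
    apply(grid, 1, paste, collapse = "")
  }
  hull <- unique(seqs)
  repeat {
    added <- FALSE
    n <- length(hull)
    if (n >= 3) {
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n) {
        qm <- majority_qm(hull[i], hull[j], hull[l])
        new <- setdiff(qm, hull)
        if (length(new)) { hull <- c(hull, new); added <- TRUE }
        if (length(hull) > max_size) return(hull)
      }
    }
    if (!added) break
  }
  hull
}
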