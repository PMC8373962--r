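# Independent reference implementations used as oracles.  These are
# deliberately written from first principles (no shared code paths with
# the package internals they check).

# O(n^3) naive Ward agglomeration: clusters are index sets; at each
# step every pair's exact increase in total within-cluster sum of
# squares is recomputed from scratch and the minimum merged (ties by
# lowest pair of current positions).  Returns the merge costs in order
# and the flat partition at each k.
naive_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ss <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- x[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(n))
  costs <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        d <- ss(c(clusters[[i]], clusters[[j]])) - ss(clusters[[i]]) - ss(clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    costs <- c(costs, best[1])
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(costs = costs, partitions = partitions)
}

# Two labelings describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + as.integer((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# Split-Rhat written independently (explicit loops over split halves).
reference_split_rhat <- function(chains_1param) {
  halves <- list()
  for (ch in chains_1param) {
    n <- length(ch)
    h <- n %/% 2
    halves[[length(halves) + 1]] <- ch[1:h]
    halves[[length(halves) + 1]] <- ch[(n - h + 1):n]
  }
  m <- length(halves)
  nn <- length(halves[[1]])
  mu <- sapply(halves, mean)
  s2 <- sapply(halves, function(v) sum((v - mean(v))^2) / (nn - 1))
  W <- sum(s2) / m
  B <- nn / (m - 1) * sum((mu - mean(mu))^2)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Numerical-convolution density of sum_k P_k (S_k + C_k) + eps for one
# tracer: each normal component's density is laid on a grid and the
# components are combined by discrete convolution, independently of
# the analytic variance-addition rule.
convolved_mixture_logpdf <- function(xvals, P, mu, omega, lambda, tau, sigma) {
  comp_mean <- c(P * mu, P * lambda, 0)
  comp_sd <- c(abs(P) * omega, abs(P) * tau, sigma)
  keep <- comp_sd > 0
  # convolve mean-centred components so every partial sum stays centred
  # on the grid; the total mean is restored as a final shift
  shift <- sum(comp_mean)
  half <- 10 * sqrt(sum(comp_sd^2)) + 1
  grid <- seq(-half, half, length.out = 2048)
  h <- grid[2] - grid[1]
  comps <- which(keep)
  dens <- stats::dnorm(grid, 0, comp_sd[comps[1]])
  for (ci in comps[-1]) {
    new <- numeric(length(grid))
    for (zi in seq_along(grid)) {
      new[zi] <- sum(dens * stats::dnorm(grid[zi] - grid, 0, comp_sd[ci])) * h
    }
    dens <- new
  }
  log(stats::approx(grid + shift, dens, xout = xvals)$y)
}

# Direct textbook Pearson r and two-tailed p from the t distribution.
reference_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

# Small canonical sample/source fixtures built in code.
toy_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    water_type = c("surface", "surface", "ground"),
    region = c("R1", "R1", "R2"),
    d15N_NO3 = c(4.5, 6.2, 14.0),
    d18O_NO3 = c(3.1, 5.0, 8.2),
    no3 = c(1.6, 2.1, 7.3),
    tn = c(1.9, 2.4, 7.5),
    nh4 = c(0.2, 0.15, 0.18),
    cond = c(310, 295, 820),
    d18O_H2O = c(-6.1, -7.2, -5.3),
    stringsAsFactors = FALSE
  )
}

toy_sources <- function() {
  make_source_profiles(
    source_id = c("CF", "MS"),
    d15N_mean = c(0, 20), d15N_sd = c(1, 2),
    d18O_mean = c(-2, 8), d18O_sd = c(1, 2)
  )
}

quick_mcmc <- function(seed = 1, n_iter = 4000, n_burn = 2000, thin = 2,
                       n_chains = 2) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
              thin = thin, rng_seed = seed)
}
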