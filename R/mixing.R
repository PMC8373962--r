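# Bayesian dual-isotope mixing model.
#
# Each observation X_ij (sample i, tracer j) is modelled as a
# proportion-weighted combination of K source signatures plus
# fractionation and residual error:
#
#   X_ij = sum_k P_k (S_jk + C_jk) + eps_ij
#   S_jk ~ N(mu_jk, omega_jk^2)   source signature
#   C_jk ~ N(lambda_jk, tau_jk^2) fractionation
#   eps_ij ~ N(0, sigma_j^2)      residual
#
# with the source and fractionation draws independent per observation.
# Marginalizing them gives the closed-form likelihood used here:
#   X_ij ~ N( sum_k P_k (mu_jk + lambda_jk),
#             sum_k P_k^2 (omega_jk^2 + tau_jk^2) + sigma_j^2 ).
# The prior is Dirichlet(1, ..., 1) on the proportions (uniform over the
# simplex) and half-Normal on each residual scale.

#' MCMC sampler configuration
#'
#' @param n_chains Number of independent chains (>= 2, so that the
#'   Gelman-Rubin diagnostic is defined).
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain (< n_iter).
#'   Proposal scales adapt only during burn-in and are frozen after, so
#'   the retained portion of each chain has detailed balance.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param proposal_scale Initial random-walk proposal standard deviation
#'   on the unconstrained scale.
#' @param rng_seed Integer seed; identical configuration implies
#'   bit-identical draws.
#' @param rhat_threshold Convergence gate: when any split-Rhat exceeds
#'   it the fit still returns draws but refuses to auto-summarize.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, n_burn = 25000L,
                        thin = 10L, proposal_scale = 0.35,
                        rng_seed = 1L, rhat_threshold = 1.05) {
  stopifnot(n_chains >= 2, n_burn < n_iter, thin >= 1, proposal_scale > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 proposal_scale = proposal_scale,
                 rng_seed = as.integer(rng_seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

# Long source table -> per-tracer matrices aligned to `tracers` order.
source_matrices <- function(sources, tracers) {
  ids <- unique(sources$source_id)
  grab <- function(col) {
    m <- matrix(NA_real_, length(tracers), length(ids),
                dimnames = list(tracers, ids))
    for (r in seq_len(nrow(sources))) {
      tr <- sources$tracer[r]
      if (tr %in% tracers) m[tr, sources$source_id[r]] <- sources[[col]][r]
    }
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("source ", ids[bad[2]], " lacks '", col, "' for tracer ",
           tracers[bad[1]])
    }
    m
  }
  list(ids = ids,
       mu = grab("mean"), omega = grab("sd"),
       lambda = grab("frac_mean"), tau = grab("frac_sd"))
}

#' Mixing-model log likelihood
#'
#' The marginalized likelihood: for proportions `P` on the K-simplex and
#' residual scales `sigma` (one per tracer), each observation is normal
#' with mean `sum_k P_k (mu_jk + lambda_jk)` and variance
#' `sum_k P_k^2 (omega_jk^2 + tau_jk^2) + sigma_j^2`.
#'
#' @param P Numeric K-vector on the simplex (non-negative, sums to 1).
#' @param sigma Positive numeric vector, one residual scale per tracer.
#' @param samples Sample data.frame holding the tracer columns.
#' @param sources Long-form source signature table.
#' @param tracers Tracer names, fixing the dimension order.
#' @return The summed log density over all samples and tracers.
#' @export
mixing_log_likelihood <- function(P, sigma, samples, sources,
                                  tracers = default_tracers()) {
  sm <- source_matrices(sources, tracers)
  if (length(P) != length(sm$ids)) stop("length(P) must equal the number of sources")
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8) stop("P must lie on the simplex")
  if (length(sigma) != length(tracers) || any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("sigma must be one finite non-negative scale per tracer")
  }
  X <- as.matrix(samples[, tracers, drop = FALSE])  # n x J
  if (any(!is.finite(X))) stop("non-finite tracer values in samples")
  mu_mix <- as.vector((sm$mu + sm$lambda) %*% P)              # J
  var_mix <- as.vector((sm$omega^2 + sm$tau^2) %*% P^2) + sigma^2
  ll <- 0
  for (j in seq_along(tracers)) {
    if (var_mix[j] == 0) {
      if (any(X[, j] != mu_mix[j])) return(-Inf)
      # degenerate point mass consistent with the data: contribute 0
    } else {
      ll <- ll + sum(stats::dnorm(X[, j], mu_mix[j], sqrt(var_mix[j]), log = TRUE))
    }
  }
  ll
}

#' Mixing-model log prior
#'
#' Dirichlet(alpha, ..., alpha) on the proportions (default alpha = 1,
#' uniform over the simplex) and independent half-Normal(scale
#' `sigma_prior_scale`) on each residual scale.  Normalizing constants
#' are included, so the value can be used directly in grid evaluation.
#'
#' @param P Proportions in the open simplex.
#' @param sigma Positive residual scales.
#' @param alpha Dirichlet concentration (scalar).
#' @param sigma_prior_scale Half-Normal scale, in per mil (default 20).
#' @return Log prior density; `-Inf` on the simplex boundary.
#' @export
mixing_log_prior <- function(P, sigma, alpha = 1, sigma_prior_scale = 20) {
  if (any(P <= 0) || abs(sum(P) - 1) > 1e-8) return(-Inf)
  if (any(sigma <= 0)) return(-Inf)
  K <- length(P)
  ld <- lgamma(K * alpha) - K * lgamma(alpha) + sum((alpha - 1) * log(P))
  lh <- sum(stats::dnorm(sigma, 0, sigma_prior_scale, log = TRUE) + log(2))
  ld + lh
}

softmax_full <- function(theta_free) {
  # theta_free has K-1 free coordinates; the last logit is pinned at 0
  z <- c(theta_free, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Fit the Bayesian mixing model to one group of samples
#'
#' Runs seeded random-walk Metropolis on the unconstrained
#' parameterization (multinomial-logit for the proportions with the
#' last logit pinned at zero, log for the residual scales), with
#' per-block proposal scales adapted during burn-in only.  Chains are
#' pooled after burn-in and thinning; split-Rhat is reported per
#' parameter.  When any Rhat exceeds the configured threshold the fit
#' warns and withholds the automatic summary (draws are still
#' returned).
#'
#' @param samples Sample data.frame for one group (>= 1 row).
#' @param sources Long-form source signature table (K sources).
#' @param mcmc An [mcmc_config()].
#' @param tracers Tracer names fixing dimension order.
#' @param alpha Dirichlet concentration of the proportion prior.
#' @param sigma_prior_scale Half-Normal prior scale for the residual
#'   scales (per mil).
#' @param sigma_fixed Optional numeric vector: fix the residual scales
#'   at these values instead of sampling them (useful for validation
#'   against low-dimensional grid evaluation).
#' @param group_label Label attached to the fit.
#' @return An object of class `"mixing_posterior"`: `draws_P` (retained
#'   draws x K, sources as columns), `draws_sigma` (retained draws x J),
#'   `chain` (chain index per retained draw), `rhat`, `accept_rate`,
#'   `summary` (NULL if the convergence gate failed), `sources`,
#'   `tracers`, `group_label`, `mcmc`.
#' @export
fit_mixing_model <- function(samples, sources, mcmc = mcmc_config(),
                             tracers = default_tracers(),
                             alpha = 1, sigma_prior_scale = 20,
                             sigma_fixed = NULL, group_label = "group") {
  sm <- source_matrices(sources, tracers)
  K <- length(sm$ids); J <- length(tracers)
  X <- as.matrix(samples[, tracers, drop = FALSE])
  if (nrow(X) < 1) stop("need at least one sample")
  if (any(!is.finite(X))) stop("non-finite tracer values in samples")
  fix_sigma <- !is.null(sigma_fixed)
  if (fix_sigma) stopifnot(length(sigma_fixed) == J, all(sigma_fixed > 0))

  A <- sm$mu + sm$lambda          # J x K mixture-mean loadings
  V <- sm$omega^2 + sm$tau^2      # J x K mixture-variance loadings
  n <- nrow(X)
  colsum_X <- colSums(X); colsum_X2 <- colSums(X^2)

  # log posterior on the unconstrained scale, including Jacobians:
  # sum(log P_k) for the logit-simplex map, sum(u) for sigma = exp(u)
  log_post <- function(theta, u) {
    P <- if (K > 1) softmax_full(theta) else 1
    sigma <- if (fix_sigma) sigma_fixed else exp(u)
    mu_mix <- as.vector(A %*% P)
    var_mix <- as.vector(V %*% P^2) + sigma^2
    if (any(var_mix <= 0)) return(-Inf)
    ll <- sum(-0.5 * log(2 * pi * var_mix) * n -
                0.5 * (colsum_X2 - 2 * mu_mix * colsum_X + n * mu_mix^2) / var_mix)
    lp <- sum((alpha - 1) * log(P)) + (if (K > 1) sum(log(P)) else 0)
    if (!fix_sigma) {
      lp <- lp + sum(-0.5 * (sigma / sigma_prior_scale)^2) + sum(u)
    }
    ll + lp
  }

  n_keep <- (mcmc$n_iter - mcmc$n_burn) %/% mcmc$thin
  if (n_keep < 1) stop("no retained draws: increase n_iter or reduce thin")
  d_theta <- max(K - 1, 0)
  d_u <- if (fix_sigma) 0 else J

  draws_P <- matrix(NA_real_, n_keep * mcmc$n_chains, K,
                    dimnames = list(NULL, sm$ids))
  draws_sigma <- matrix(NA_real_, n_keep * mcmc$n_chains, J,
                        dimnames = list(NULL, tracers))
  chain_id <- integer(n_keep * mcmc$n_chains)
  accept_rate <- numeric(mcmc$n_chains)

  set.seed(mcmc$rng_seed %% .Machine$integer.max)
  for (ch in seq_len(mcmc$n_chains)) {
    theta <- rep(0, d_theta)
    u <- if (fix_sigma) numeric(0) else rep(log(stats::sd(X) + 0.5), d_u)
    scale_theta <- mcmc$proposal_scale
    scale_u <- mcmc$proposal_scale
    # adaptive proposal shape for the proportion block: during burn-in
    # the empirical covariance of the logit draws is folded into a
    # Cholesky factor (Haario-style adaptive Metropolis); the shape and
    # the scales are frozen after burn-in to preserve detailed balance
    chol_theta <- if (d_theta > 0) diag(d_theta) else NULL
    hist_theta <- if (d_theta > 0)
      matrix(NA_real_, min(mcmc$n_burn, 5000L), d_theta) else NULL
    hist_n <- 0L
    lp_cur <- log_post(theta, u)
    acc_theta <- 0L; acc_u <- 0L; n_acc <- 0L; n_post <- 0L
    row0 <- (ch - 1L) * n_keep
    kept <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      if (d_theta > 0) {
        step <- as.vector(chol_theta %*% stats::rnorm(d_theta)) * scale_theta
        prop <- theta + step
        lp_prop <- log_post(prop, u)
        if (log(stats::runif(1)) < lp_prop - lp_cur) {
          theta <- prop; lp_cur <- lp_prop; acc_theta <- acc_theta + 1L
          if (it > mcmc$n_burn) n_acc <- n_acc + 1L
        }
        if (it <= mcmc$n_burn && hist_n < nrow(hist_theta)) {
          hist_n <- hist_n + 1L
          hist_theta[hist_n, ] <- theta
        }
      }
      if (d_u > 0) {
        prop_u <- u + stats::rnorm(d_u, 0, scale_u)
        lp_prop <- log_post(theta, prop_u)
        if (log(stats::runif(1)) < lp_prop - lp_cur) {
          u <- prop_u; lp_cur <- lp_prop; acc_u <- acc_u + 1L
          if (it > mcmc$n_burn) n_acc <- n_acc + 1L
        }
      }
      if (it > mcmc$n_burn) n_post <- n_post + 1L
      # adapt proposal scales and shape during burn-in only
      if (it <= mcmc$n_burn && it %% 100L == 0L) {
        if (d_theta > 0) {
          r <- acc_theta / 100
          scale_theta <- scale_theta * exp(0.5 * (r - 0.3))
          acc_theta <- 0L
          if (it %% 1000L == 0L && hist_n > 10L * d_theta) {
            cv <- stats::cov(hist_theta[seq_len(hist_n), , drop = FALSE])
            cv <- cv + diag(1e-6, d_theta)
            ch_try <- tryCatch(t(chol(cv)), error = function(e) NULL)
            if (!is.null(ch_try)) {
              # normalize so scale_theta keeps its meaning
              chol_theta <- ch_try / exp(mean(log(diag(ch_try))))
            }
          }
        }
        if (d_u > 0) {
          r <- acc_u / 100
          scale_u <- scale_u * exp(0.5 * (r - 0.3))
          acc_u <- 0L
        }
      }
      if (it > mcmc$n_burn && (it - mcmc$n_burn) %% mcmc$thin == 0L &&
          kept < n_keep) {
        kept <- kept + 1L
        P <- if (K > 1) softmax_full(theta) else 1
        draws_P[row0 + kept, ] <- P / sum(P)
        draws_sigma[row0 + kept, ] <- if (fix_sigma) sigma_fixed else exp(u)
        chain_id[row0 + kept] <- ch
      }
    }
    blocks <- (d_theta > 0) + (d_u > 0)
    accept_rate[ch] <- if (n_post > 0 && blocks > 0) n_acc / (n_post * blocks) else NA_real_
  }

  # convergence diagnostics on the per-chain retained draws
  param_mats <- lapply(seq_len(mcmc$n_chains), function(ch) {
    idx <- chain_id == ch
    cbind(draws_P[idx, , drop = FALSE],
          if (!fix_sigma) draws_sigma[idx, , drop = FALSE])
  })
  rhat <- convergence_diagnostics(param_mats)

  converged <- all(is.na(rhat) | rhat <= mcmc$rhat_threshold)
  post <- structure(list(
    draws_P = draws_P, draws_sigma = draws_sigma, chain = chain_id,
    rhat = rhat, accept_rate = accept_rate,
    summary = NULL, converged = converged,
    sources = sources, tracers = tracers,
    group_label = group_label, mcmc = mcmc
  ), class = "mixing_posterior")
  if (converged) {
    post$summary <- summarize_posterior(post)
  } else {
    warning("split-Rhat above ", mcmc$rhat_threshold, " for group '",
            group_label, "'; summary withheld (draws returned)")
  }
  post
}

#' Summarize a mixing posterior as a contribution-rate table
#'
#' Per source: posterior mean and SD of the contribution in percent,
#' rounded to one decimal.  Sources are ordered CF, MS, NP, SN when all
#' of those ids are present, otherwise in input order.  The per-tracer
#' posterior-mean residual scales are attached as the
#' `"sigma_mean"` attribute.
#'
#' @param posterior A `"mixing_posterior"`.
#' @return A data.frame with columns `group`, `source`, `mean_pct`,
#'   `sd_pct`.
#' @export
summarize_posterior <- function(posterior) {
  stopifnot(inherits(posterior, "mixing_posterior"))
  P <- posterior$draws_P
  if (nrow(P) < 1) stop("posterior has no retained draws")
  ids <- colnames(P)
  canonical <- c("CF", "MS", "NP", "SN")
  ord <- if (all(canonical %in% ids)) {
    c(match(canonical, ids), setdiff(seq_along(ids), match(canonical, ids)))
  } else seq_along(ids)
  means <- colMeans(P) * 100
  sds <- apply(P, 2, stats::sd) * 100
  out <- data.frame(group = posterior$group_label,
                    source = ids[ord],
                    mean_pct = round(means[ord], 1),
                    sd_pct = round(sds[ord], 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma_mean") <- colMeans(posterior$draws_sigma)
  out
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Bayesian mixing posterior for group '", x$group_label, "': ",
      nrow(x$draws_P), " retained draws, ", max(x$chain), " chains\n", sep = "")
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$summary)) {
    cat("  contribution rates (mean +/- SD, %):\n")
    for (r in seq_len(nrow(x$summary))) {
      cat(sprintf("    %-3s %5.1f +/- %4.1f\n", x$summary$source[r],
                  x$summary$mean_pct[r], x$summary$sd_pct[r]))
    }
  }
  invisible(x)
}

#' Split-Rhat convergence diagnostic
#'
#' Plain (non-rank-normalized) split-Rhat: each chain is split in half,
#' and the usual Gelman-Rubin ratio of pooled to within-chain variance
#' is computed over the split halves.  Values near 1 indicate that the
#' chains have mixed.
#'
#' @param chains List (one element per chain, >= 2) of numeric matrices,
#'   retained draws x parameters, all the same shape.
#' @return Named numeric vector of Rhat values, one per parameter
#'   (NA for parameters with zero variance everywhere, e.g. pinned
#'   degenerate proportions).
#' @export
convergence_diagnostics <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("convergence_diagnostics needs >= 2 chains")
  }
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  if (n < 10) stop("need >= 10 retained draws per chain")
  if (any(vapply(chains, nrow, 1L) != n)) stop("chains must have equal length")
  half <- n %/% 2
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1L]] <- ch[(n - half + 1):n, , drop = FALSE]
  }
  m <- length(splits)
  p <- ncol(chains[[1]])
  rhat <- numeric(p)
  for (jp in seq_len(p)) {
    means <- vapply(splits, function(s) mean(s[, jp]), numeric(1))
    vars <- vapply(splits, function(s) stats::var(s[, jp]), numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) {
      rhat[jp] <- if (B == 0) NA_real_ else Inf
    } else {
      var_plus <- (half - 1) / half * W + B / half
      rhat[jp] <- sqrt(var_plus / W)
    }
  }
  names(rhat) <- colnames(chains[[1]])
  rhat
}
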