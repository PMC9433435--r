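#' Bayesian MCMC ancestral state reconstruction at a focal clade
#'
#' Metropolis-Hastings sampling of an all-rates-different Mk model with a
#' hierarchical prior: each rate is exponential with mean m, and m is itself
#' uniform on `prior_mean_range` (default (0, 30)), mirroring the
#' hyper-prior idiom of trait MCMC software. Each iteration draws one input
#' tree uniformly (so a posterior tree sample can be integrated over),
#' updates the rates and hyper-mean, and records the marginal posterior
#' state probabilities at the most recent common ancestor of `focal_clade`.
#'
#' Iterations whose state probabilities are essentially flat (max
#' probability <= 1/k + 0.02, i.e. "0.2 for each state" with five states)
#' are discarded as equivocal. The remaining samples are averaged per chain
#' and across chains; a state is called supported only when its averaged
#' probability exceeds 0.7. Effective sample sizes are computed per chain on
#' the focal-state trace and chains with ESS < 200 are flagged.
#'
#' @param trees A `dated_tree` or list of them.
#' @param traits A `trait_table`.
#' @param focal_clade Character vector of taxa whose MRCA is the focal node.
#' @param prior_mean_range Range of the uniform hyper-prior on the
#'   exponential mean (events/Ma scale).
#' @param n_chains,n_iter,burn_in Chains, iterations per chain, burn-in
#'   fraction. Desk-scale defaults: 3 chains x 30,000 iterations, 25%.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param root_prior Root prior for the pruning likelihood. The default is
#'   the stationary distribution of the sampled rate matrix: under an
#'   all-rates model a uniform root prior lets high-return-rate regimes
#'   (which erase the root state) dominate the posterior, whereas the
#'   stationary prior treats the root as a draw from the process itself.
#' @param scale_branches Rescale branch durations so the mean branch length
#'   is 0.1 before sampling (the trait-MCMC convention that keeps the
#'   (0, 30) rate prior on a scale where both negligible and saturating
#'   rates are reachable); reported state probabilities are unaffected by
#'   the parameterisation, only sampling efficiency is.
#' @return Object of class `bayes_asr`: `posterior` (tibble state x mean
#'   probability), `chain_means`, `support_call`, `ess`, `n_used`,
#'   `n_discarded`, `ess_ok`.
#' @export
bayes_asr <- function(trees, traits, focal_clade,
                      prior_mean_range = c(0, 30),
                      n_chains = 3, n_iter = 30000, burn_in = 0.25,
                      seed = 1, root_prior = "stationary",
                      scale_branches = TRUE) {
  if (inherits(trees, "dated_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  if (length(focal_clade) == 0) stop("empty focal clade")
  if (burn_in >= 1) stop("burn_in must be a fraction < 1 of n_iter")
  states <- trait_states(traits)
  k <- length(states)
  np <- k * (k - 1)
  n_burn <- floor(n_iter * burn_in)
  if (n_burn >= n_iter) stop("burn-in leaves no samples")

  # per-tree cached quantities; optionally rescale to mean branch 0.1
  prep <- lapply(trees, function(tr) {
    if (scale_branches) {
      phy <- tr$phylo
      phy$edge.length <- phy$edge.length * 0.1 / mean(phy$edge.length)
      tr <- parse_tree(phy)
    }
    list(tree = tr, focal = find_mrca(tr, intersect(focal_clade, tr$phylo$tip.label)))
  })
  loglik <- function(lr, pi) {
    mk_loglik_Q(pi$tree, traits, mk_rate_matrix(exp(lr), k, "asymm"), root_prior)
  }
  log_prior <- function(lr, m) {
    if (m <= prior_mean_range[1] || m >= prior_mean_range[2]) return(-Inf)
    r <- exp(lr)
    # exponential density on rates plus log-Jacobian of the log transform
    sum(-log(m) - r / m + lr)
  }

  chain_means <- matrix(NA_real_, n_chains, k, dimnames = list(NULL, states))
  ess <- numeric(n_chains)
  used <- disc <- integer(n_chains)
  all_samples <- vector("list", n_chains)
  for (chain in seq_len(n_chains)) {
    set.seed(seed + chain)
    m <- runif(1, prior_mean_range[1] + 1e-6, prior_mean_range[2])
    lr <- log(rexp(np, 1 / max(m, 1e-6)) + 1e-8)
    ti <- sample.int(length(prep), 1)
    cur_ll <- loglik(lr, prep[[ti]])
    cur_lp <- log_prior(lr, m)
    probs <- matrix(NA_real_, n_iter, k)
    for (it in seq_len(n_iter)) {
      ti <- sample.int(length(prep), 1)
      cur_ll <- loglik(lr, prep[[ti]])  # tree refreshed each iteration
      # rate update: mixture of walk / joint-scale / prior-independence moves
      u <- runif(1)
      lhr <- 0  # log Hastings ratio
      if (u < 0.5) {
        j <- sample.int(np, 1)
        lr2 <- lr
        lr2[j] <- lr[j] + stats::rnorm(1, 0, 0.6)
      } else if (u < 0.75) {
        lr2 <- lr + stats::rnorm(1, 0, 0.8)  # scale all rates jointly
      } else {
        r_new <- rexp(np, 1 / m)  # independence draw from the prior
        lr2 <- log(r_new + 1e-12)
        lhr <- log_prior(lr, m) - log_prior(lr2, m)
      }
      new_ll <- loglik(lr2, prep[[ti]])
      new_lp <- log_prior(lr2, m)
      if (is.finite(new_ll) &&
          log(runif(1)) < (new_ll + new_lp) - (cur_ll + cur_lp) + lhr) {
        lr <- lr2; cur_ll <- new_ll; cur_lp <- new_lp
      }
      # hyper-mean update (prior-only MH step)
      m2 <- m + stats::rnorm(1, 0, 1.5)
      lp2 <- log_prior(lr, m2)
      if (is.finite(lp2) && log(runif(1)) < lp2 - cur_lp) {
        m <- m2; cur_lp <- lp2
      }
      marg <- mk_marginals(prep[[ti]]$tree, traits,
                           mk_rate_matrix(exp(lr), k, "asymm"), root_prior)
      probs[it, ] <- marg[prep[[ti]]$focal, ]
    }
    keep <- probs[(n_burn + 1):n_iter, , drop = FALSE]
    flat <- apply(keep, 1, max) <= 1 / k + 0.02
    used[chain] <- sum(!flat); disc[chain] <- sum(flat)
    if (used[chain] == 0) {
      chain_means[chain, ] <- rep(1 / k, k)
    } else {
      chain_means[chain, ] <- colMeans(keep[!flat, , drop = FALSE])
    }
    top <- which.max(chain_means[chain, ])
    ess[chain] <- ess_iact(keep[, top])
    all_samples[[chain]] <- keep
  }
  post <- colMeans(chain_means)
  call <- if (max(post) > 0.7) states[which.max(post)]
  else if (max(post) <= 1 / k + 0.02) "equivocal" else "unsupported"
  structure(
    list(posterior = tibble(state = states, probability = unname(post)),
         chain_means = chain_means, support_call = call,
         ess = ess, ess_ok = all(ess >= 200),
         n_used = used, n_discarded = disc, n_chains = n_chains,
         states = states),
    class = "bayes_asr")
}

#' @export
print.bayes_asr <- function(x, ...) {
  cat("<bayes_asr>", x$n_chains, "chains; support call:", x$support_call, "\n")
  p <- x$posterior
  cat(paste0("  ", p$state, ": ", format(round(p$probability, 4))), sep = "\n")
  if (!x$ess_ok) cat("  [warning: ESS < 200 in at least one chain]\n")
  invisible(x)
}

# effective sample size from the integrated autocorrelation time, with
# Geyer-style truncation at the first non-positive even-lag pair sum
ess_iact <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  lag_max <- min(n - 1, 1000)
  ac <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
  s <- 0
  i <- 1
  while (i <= length(ac) - 1) {
    pair <- ac[i] + ac[i + 1]
    if (pair <= 0) break
    s <- s + pair
    i <- i + 2
  }
  n / (1 + 2 * s)
}
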