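#' Mk models of discrete character evolution
#'
#' Continuous-time Markov models over k states on a dated tree, with branch
#' durations in Ma. `Mk1` has a single rate for every ordered state pair;
#' `AsymmMk` allows every ordered pair its own rate (k(k-1) parameters; for
#' k = 2 this is the classic forward/backward two-parameter model). The
#' likelihood is computed by Felsenstein pruning; the root prior defaults to
#' uniform over states.
#'
#' @name mk_models
NULL

# build a k x k rate matrix from model + rates
mk_rate_matrix <- function(rates, k, model = c("mk1", "asymm")) {
  model <- match.arg(model)
  if (any(rates < 0)) stop("negative rates are not allowed")
  Q <- matrix(0, k, k)
  if (model == "mk1") {
    stopifnot(length(rates) == 1)
    Q[] <- rates
  } else {
    stopifnot(length(rates) == k * (k - 1))
    m <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      m <- m + 1L
      Q[i, j] <- rates[m]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrices for all branches: eigen decomposition with
# a scaling-and-squaring fallback for defective rate settings
mk_transition_probs <- function(Q, times) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- !is.null(eg) && all(is.finite(abs(eg$vectors)))
  Vinv <- NULL
  if (use_eigen) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    use_eigen <- !is.null(Vinv) && all(is.finite(abs(Vinv)))
  }
  lapply(times, function(t) {
    P <- if (use_eigen) {
      Re(eg$vectors %*% (exp(eg$values * t) * Vinv))
    } else {
      ape::matexpo(Q * t)
    }
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

# pruning partials for every node; returns list(partials (n_all x k), logscale)
mk_partials <- function(tree, tip_state_idx, k, P_edge) {
  po <- tree_postorder_edges(tree)
  n_all <- tree$n_tip + tree$n_node
  L <- matrix(1, n_all, k)
  for (i in seq_len(tree$n_tip)) {
    L[i, ] <- 0
    L[i, tip_state_idx[i]] <- 1
  }
  logscale <- numeric(n_all)
  edges_by_parent <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (v in unique(po$edge[, 1])) {
    for (e in edges_by_parent[[as.character(v)]]) {
      ch <- po$edge[e, 2]
      L[v, ] <- L[v, ] * as.vector(P_edge[[e]] %*% L[ch, ])
      logscale[v] <- logscale[v] + logscale[ch]
    }
    mx <- max(L[v, ])
    if (mx <= 0) return(NULL)  # impossible data under this Q
    L[v, ] <- L[v, ] / mx
    logscale[v] <- logscale[v] + log(mx)
  }
  list(partials = L, logscale = logscale, po = po)
}

#' Mk log-likelihood of a discrete character
#'
#' @param tree A `dated_tree` (branch durations in Ma).
#' @param traits A `trait_table`.
#' @param rates Rate(s): length 1 for `mk1`, length k(k-1) (row-major over
#'   ordered pairs) for `asymm`.
#' @param model `"mk1"` or `"asymm"`.
#' @param root_prior `"uniform"` (1/k, the Mesquite default), `"stationary"`,
#'   or a numeric k-vector.
#' @return Log-likelihood (scalar).
#' @export
mk_log_likelihood <- function(tree, traits, rates, model = c("mk1", "asymm"),
                              root_prior = "uniform") {
  model <- match.arg(model)
  states <- trait_states(traits)
  k <- length(states)
  Q <- mk_rate_matrix(rates, k, model)
  mk_loglik_Q(tree, traits, Q, root_prior)
}

mk_root_prior <- function(root_prior, Q, k) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k)
    return(root_prior / sum(root_prior))
  }
  if (identical(root_prior, "stationary")) {
    ns <- MASS_null_stationary(Q)
    return(ns)
  }
  rep(1 / k, k)
}

# stationary distribution of Q (left null vector)
MASS_null_stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- tryCatch(qr.solve(A, b), error = function(e) rep(1 / k, k))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

mk_loglik_Q <- function(tree, traits, Q, root_prior = "uniform") {
  if (max(abs(rowSums(Q))) > 1e-8) stop("rate matrix rows must sum to 0")
  states <- trait_states(traits)
  k <- length(states)
  tip_idx <- match(states_for_tree(tree, traits), states)
  po <- tree_postorder_edges(tree)
  P_edge <- mk_transition_probs(Q, po$length)
  pr <- mk_partials(tree, tip_idx, k, P_edge)
  if (is.null(pr)) return(-Inf)
  prior <- mk_root_prior(root_prior, Q, k)
  root <- tree$root
  lik <- sum(prior * pr$partials[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[root]
}

# marginal ancestral state probabilities by the up-down algorithm
mk_marginals <- function(tree, traits, Q, root_prior = "uniform") {
  states <- trait_states(traits)
  k <- length(states)
  tip_idx <- match(states_for_tree(tree, traits), states)
  po <- tree_postorder_edges(tree)
  P_edge <- mk_transition_probs(Q, po$length)
  pr <- mk_partials(tree, tip_idx, k, P_edge)
  if (is.null(pr)) stop("data impossible under this rate matrix")
  Lp <- pr$partials
  n_all <- tree$n_tip + tree$n_node
  prior <- mk_root_prior(root_prior, Q, k)
  # down-contribution of each edge: D_e[s_parent] = (P_e %*% L_child)[s_parent]
  edge_down <- lapply(seq_len(nrow(po$edge)), function(e) {
    as.vector(P_edge[[e]] %*% Lp[po$edge[e, 2], ])
  })
  U <- matrix(0, n_all, k)
  U[tree$root, ] <- prior
  child_edges <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (v in rev(unique(po$edge[, 1]))) {  # preorder over internal nodes
    es <- child_edges[[as.character(v)]]
    for (e in es) {
      ch <- po$edge[e, 2]
      sib_prod <- U[v, ]
      for (e2 in setdiff(es, e)) sib_prod <- sib_prod * edge_down[[e2]]
      u <- as.vector(sib_prod %*% P_edge[[e]])
      if (max(u) > 0) u <- u / max(u)
      U[ch, ] <- u
    }
  }
  M <- U * Lp
  sw <- rowSums(M)
  sw[sw <= 0] <- 1
  M <- M / sw
  colnames(M) <- states
  M
}

#' Fit an Mk model by maximum likelihood
#'
#' Bounded 1-D optimisation (`mk1`) or multi-parameter L-BFGS-B on log rates
#' (`asymm`, initialised from the Mk1 fit). A constant character drives the
#' rate to the lower bound; this is reported via `boundary = TRUE` rather
#' than silently clamped.
#'
#' @inheritParams mk_log_likelihood
#' @param lower,upper Rate bounds (events/Ma).
#' @return Object of class `mk_fit`: `model`, `rates`, `Q`,
#'   `log_likelihood`, `anc_prob` (node x state marginal matrix),
#'   `root_prior`, `npar`, `boundary`, `convergence`.
#' @export
fit_mk <- function(tree, traits, model = c("mk1", "asymm"),
                   root_prior = "uniform", lower = 1e-9, upper = 1e3) {
  model <- match.arg(model)
  states <- trait_states(traits)
  k <- length(states)
  nll1 <- function(logq) {
    -mk_log_likelihood(tree, traits, exp(logq), "mk1", root_prior)
  }
  opt1 <- optimize(nll1, c(log(lower), log(upper)), tol = 1e-8)
  q1 <- exp(opt1$minimum)
  if (model == "mk1") {
    rates <- q1
    ll <- -opt1$objective
    conv <- 0L
  } else {
    np <- k * (k - 1)
    nllm <- function(lr) {
      v <- -mk_loglik_Q(tree, traits, mk_rate_matrix(exp(lr), k, "asymm"), root_prior)
      if (!is.finite(v)) 1e10 else v
    }
    init <- rep(log(q1), np)
    o <- optim(init, nllm, method = "L-BFGS-B",
               lower = log(lower), upper = log(upper),
               control = list(maxit = 500, factr = 1e4))
    # a second start from jittered values guards against flat regions
    o2 <- optim(init + stats::rnorm(np, 0, 0.5), nllm, method = "L-BFGS-B",
                lower = log(lower), upper = log(upper),
                control = list(maxit = 500, factr = 1e4))
    if (o2$value < o$value) o <- o2
    rates <- exp(o$par)
    ll <- -o$value
    conv <- o$convergence
  }
  Q <- mk_rate_matrix(rates, k, model)
  boundary <- any(abs(log(rates) - log(lower)) < 1e-6)
  anc <- mk_marginals(tree, traits, Q, root_prior)
  structure(
    list(model = model, rates = rates, Q = Q, log_likelihood = ll,
         anc_prob = anc, root_prior = root_prior,
         npar = length(rates), boundary = boundary, convergence = conv,
         states = states, tree = tree),
    class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit>", x$model, "- logLik", format(x$log_likelihood, digits = 8),
      "-", x$npar, "rate(s)", if (x$boundary) "[rate at lower bound]" else "", "\n")
  invisible(x)
}

#' Likelihood-ratio test of Mk1 against AsymmMk
#'
#' Statistic 2(l_asymm - l_mk1), df = k(k-1) - 1, p from the chi-squared
#' distribution. The statistic is non-negative up to optimiser tolerance.
#'
#' @param fit_mk1 An `mk_fit` with model `"mk1"`.
#' @param fit_asymm An `mk_fit` with model `"asymm"`.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
mk_lrt <- function(fit_mk1, fit_asymm) {
  stopifnot(fit_mk1$model == "mk1", fit_asymm$model == "asymm")
  stat <- 2 * (fit_asymm$log_likelihood - fit_mk1$log_likelihood)
  if (stat < -1e-6) warning("AsymmMk log-likelihood below Mk1: optimiser failure")
  stat <- max(stat, 0)
  df <- fit_asymm$npar - 1L
  tibble(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}
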