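#' Goldman-Yang (GY94) codon substitution models
#'
#' Codon-level Markov models over the sense codons of the bound genetic
#' code, with transition/transversion ratio kappa, selection parameter
#' omega acting on nonsynonymous changes, and target codon frequencies pi.
#' Site models: M0 (one omega), M1a (nearly neutral: omega0 < 1 with
#' proportion p0, omega1 = 1), M2a (adds a positive-selection class
#' omega2 > 1). Branch lengths are clock-proportional: the dated tree's
#' durations (Ma) times one free tree-scale parameter rho (expected
#' substitutions per codon per Ma, averaged over site classes).
#'
#' @name gy94
NULL

#' GY94 instantaneous rate matrix (unscaled)
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param pi Codon frequencies over the sense codons (sums to 1).
#' @param code A [genetic_code()].
#' @return List: `Q` (n_sense x n_sense, rows sum to 0, unscaled), `rate`
#'   (mean substitution rate under `pi`), satisfying detailed balance
#'   pi_i q_ij = pi_j q_ji.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi, code = genetic_code(5)) {
  ty <- code$pair_type
  n <- length(code$sense)
  stopifnot(length(pi) == n)
  fac <- matrix(0, n, n)
  fac[ty == 1L] <- kappa
  fac[ty == 2L] <- 1
  fac[ty == 3L] <- kappa * omega
  fac[ty == 4L] <- omega
  Q <- fac * rep(pi, each = n)  # q_ij = fac_ij * pi_j
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

#' Codon frequencies from an alignment
#'
#' `f3x4` multiplies per-position nucleotide frequencies and renormalises
#' over sense codons (the CodeML default); `empirical` uses observed codon
#' counts with one pseudo-count spread over the sense codons.
#'
#' @param aln A `codon_alignment`.
#' @param method `"f3x4"` or `"empirical"`.
#' @return Frequency vector named by sense codon.
#' @export
codon_frequencies <- function(aln, method = c("f3x4", "empirical")) {
  method <- match.arg(method)
  code <- aln$code
  obs <- aln$codons[!aln$mask]
  if (method == "empirical") {
    cnt <- table(factor(obs, levels = code$sense))
    p <- (as.numeric(cnt) + 1 / length(code$sense))
    return(setNames(p / sum(p), code$sense))
  }
  ch <- codon_chars(obs)
  nts <- c("A", "C", "G", "T")
  posfreq <- vapply(1:3, function(p) {
    tab <- table(factor(ch[, p], levels = nts))
    as.numeric(tab) / max(sum(tab), 1)
  }, numeric(4))
  sense_ch <- codon_chars(code$sense)
  p <- posfreq[match(sense_ch[, 1], nts), 1] *
    posfreq[match(sense_ch[, 2], nts), 2] *
    posfreq[match(sense_ch[, 3], nts), 3]
  p <- pmax(p, 1e-12)
  setNames(p / sum(p), code$sense)
}

# site-pattern compression: 0-based states for the C++ pruning kernel
codon_tip_patterns <- function(tree, aln) {
  tips <- tree$phylo$tip.label
  idx <- match(tips, aln$taxa)
  if (anyNA(idx)) stop("alignment missing taxa: ", paste(tips[is.na(idx)], collapse = ", "))
  code <- aln$code
  st <- matrix(match(aln$codons[idx, , drop = FALSE], code$sense) - 1L,
               nrow = length(tips))
  st[aln$mask[idx, , drop = FALSE]] <- -1L
  key <- apply(st, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_index <- match(key, key[upat])
  list(states = st[, upat, drop = FALSE],
       weights = as.numeric(table(factor(pat_index, levels = seq_len(sum(upat))))),
       pat_index = pat_index)
}

# per-class per-pattern log-likelihood matrix (nclass x npat)
codon_class_logliks <- function(tree, pat, kappa, omegas, probs, rho, pi,
                                code = genetic_code(5)) {
  po <- tree_postorder_edges(tree)
  mats <- lapply(omegas, function(w) gy94_rate_matrix(kappa, w, pi, code))
  Fbar <- sum(probs * vapply(mats, `[[`, 0, "rate"))
  scale <- rho / Fbar
  t(vapply(mats, function(m) {
    cpp_codon_site_loglik(m$Q, pi, po$edge, po$length * scale,
                          tree$n_tip, pat$states, pi)
  }, numeric(ncol(pat$states))))
}

# mixture log-likelihood over patterns
codon_mixture_loglik <- function(class_ll, probs, weights) {
  mx <- apply(class_ll, 2, max)
  if (any(!is.finite(mx))) return(-Inf)
  site_ll <- mx + log(colSums(exp(sweep(class_ll, 2, mx)) * probs))
  sum(site_ll * weights)
}

site_model_pars <- function(model) {
  switch(model,
    M0  = list(n = 3, names = c("log_rho", "log_kappa", "log_omega")),
    M1a = list(n = 4, names = c("log_rho", "log_kappa", "logit_p0", "logit_omega0")),
    M2a = list(n = 6, names = c("log_rho", "log_kappa", "a1", "a2",
                                "logit_omega0", "log_omega2m1")))
}

site_model_classes <- function(model, theta) {
  plogis <- stats::plogis
  if (model == "M0") {
    list(omegas = exp(theta[3]), probs = 1)
  } else if (model == "M1a") {
    p0 <- plogis(theta[3])
    list(omegas = c(plogis(theta[4]), 1), probs = c(p0, 1 - p0))
  } else {
    e <- exp(c(theta[3], theta[4], 0))
    probs <- e / sum(e)
    list(omegas = c(plogis(theta[5]), 1, 1 + exp(theta[6])), probs = probs)
  }
}

site_model_bounds <- function(model) {
  # kappa in [0.1, 50], omega in [1e-4, 20] per the optimisation contract
  lw <- c(-14, log(0.1)); up <- c(3, log(50))
  if (model == "M0") {
    lw <- c(lw, log(1e-4)); up <- c(up, log(20))
  } else if (model == "M1a") {
    lw <- c(lw, -8, stats::qlogis(1e-4)); up <- c(up, 8, stats::qlogis(0.9999))
  } else {
    lw <- c(lw, -8, -8, stats::qlogis(1e-4), log(1e-6))
    up <- c(up, 8, 8, stats::qlogis(0.9999), log(19))
  }
  list(lower = lw, upper = up)
}

# crude initial tree scale from mean pairwise codon mismatch
init_tree_scale <- function(tree, aln) {
  n <- length(aln$taxa)
  pairs <- utils::combn(seq_len(min(n, 6)), 2)
  d <- mean(apply(pairs, 2, function(p) {
    ok <- !aln$mask[p[1], ] & !aln$mask[p[2], ]
    if (!any(ok)) return(0.1)
    mean(aln$codons[p[1], ok] != aln$codons[p[2], ok])
  }))
  max(d, 0.02) / (2 * max(root_age(tree), 1))
}

#' Fit a GY94 site model by maximum likelihood
#'
#' Bounded multistart L-BFGS-B on transformed parameters. The mixture
#' likelihood is the per-site sum over omega classes weighted by their
#' proportions; with a single class it equals the M0 likelihood at that
#' omega. For M2a a Naive Empirical Bayes posterior membership of the
#' positive-selection class is computed at the MLEs; a site is called
#' positively selected only when that posterior is at least 0.95.
#'
#' @param tree A `dated_tree`.
#' @param aln A `codon_alignment`.
#' @param model `"M0"`, `"M1a"` or `"M2a"`.
#' @param pi_method Codon frequency estimator, see [codon_frequencies()].
#' @param n_starts Number of optimisation starts (first is heuristic,
#'   others jittered).
#' @param seed Seed for the start jitter.
#' @param init Optional named list with starting `kappa`, `omega`, `rho`.
#' @param chain_from Optional nested `site_model_fit` used as a warm start
#'   (M0 for M1a, M1a for M2a).
#' @param control `optim` control list; the default stops at roughly 1e-6
#'   on the log-likelihood, which resolves the likelihood surface well
#'   inside the statistical uncertainty of these models.
#' @return Object of class `site_model_fit`: `model`, `log_likelihood`,
#'   `kappa`, `omegas`, `probs`, `rho`, `pi`, `npar`, `site_posterior`
#'   (M2a: per-codon-site posterior of the positive class), `convergence`.
#' @export
fit_site_model <- function(tree, aln, model = c("M0", "M1a", "M2a"),
                           pi_method = "f3x4", n_starts = 5, seed = 1,
                           init = NULL, chain_from = NULL,
                           control = list(maxit = 200, factr = 1e7)) {
  model <- match.arg(model)
  pi <- codon_frequencies(aln, pi_method)
  pat <- codon_tip_patterns(tree, aln)
  code <- aln$code
  bounds <- site_model_bounds(model)
  nll <- function(theta) {
    cl <- site_model_classes(model, theta)
    ll <- codon_mixture_loglik(
      codon_class_logliks(tree, pat, exp(theta[2]), cl$omegas, cl$probs,
                          exp(theta[1]), pi, code),
      cl$probs, pat$weights)
    if (!is.finite(ll)) 1e10 else -ll
  }
  rho0 <- if (!is.null(init$rho)) init$rho else init_tree_scale(tree, aln)
  kap0 <- if (!is.null(init$kappa)) init$kappa else 2
  om0 <- if (!is.null(init$omega)) init$omega else 0.3
  if (!is.null(chain_from)) {
    # warm start from the next-simpler nested fit
    rho0 <- chain_from$rho
    kap0 <- chain_from$kappa
    om0 <- min(chain_from$omegas[1], 0.95)
  }
  clamp01 <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
  base <- switch(model,
    M0  = c(log(rho0), log(kap0), log(om0)),
    M1a = c(log(rho0), log(kap0),
            stats::qlogis(if (!is.null(chain_from) && chain_from$model == "M0")
              0.85 else 0.7),
            stats::qlogis(clamp01(min(om0, 0.9)))),
    M2a = if (!is.null(chain_from) && chain_from$model == "M1a") {
      p0 <- clamp01(chain_from$probs[1]); p1 <- clamp01(chain_from$probs[2])
      p2 <- 0.05
      sc <- (1 - p2) / (p0 + p1)
      c(log(rho0), log(kap0), log(p0 * sc / p2), log(p1 * sc / p2),
        stats::qlogis(clamp01(chain_from$omegas[1])), log(0.5))
    } else {
      c(log(rho0), log(kap0), stats::qlogis(0.6), 0,
        stats::qlogis(clamp01(min(om0, 0.9))), log(1))
    })
  base <- pmin(pmax(base, bounds$lower), bounds$upper)
  set.seed(seed)
  # second deterministic start for M2a probes a clearly positive omega2
  alt <- if (model == "M2a") {
    a <- base; a[3:4] <- c(log(0.6 / 0.15), log(0.25 / 0.15)); a[6] <- log(2)
    pmin(pmax(a, bounds$lower), bounds$upper)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) base else if (s == 2 && !is.null(alt)) alt else {
      pmin(pmax(base + stats::rnorm(length(base), 0, 0.7), bounds$lower), bounds$upper)
    }
    o <- tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = bounds$lower,
            upper = bounds$upper, control = control),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("site model optimisation failed after ", n_starts, " starts")
  th <- best$par
  cl <- site_model_classes(model, th)
  post <- NULL
  if (model == "M2a") {
    class_ll <- codon_class_logliks(tree, pat, exp(th[2]), cl$omegas, cl$probs,
                                    exp(th[1]), pi, code)
    w <- exp(sweep(class_ll, 2, apply(class_ll, 2, max))) * cl$probs
    post_pat <- w[3, ] / colSums(w)
    post <- post_pat[pat$pat_index]
  }
  structure(
    list(model = model, log_likelihood = -best$value,
         kappa = exp(th[2]), omegas = cl$omegas, probs = cl$probs,
         rho = exp(th[1]), pi = pi, npar = length(th),
         site_posterior = post, pos_site_threshold = 0.95,
         convergence = best$convergence, n_starts = n_starts,
         gene = aln$gene),
    class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("<site_model_fit>", x$model, "on", x$gene,
      "- logLik", format(x$log_likelihood, digits = 8),
      "- kappa", format(x$kappa, digits = 3),
      "- omega", paste(format(x$omegas, digits = 3), collapse = "/"),
      "- p", paste(format(x$probs, digits = 3), collapse = "/"), "\n")
  invisible(x)
}

#' Likelihood-ratio test of M1a against M2a
#'
#' Statistic 2(l_M2a - l_M1a), df = 2, p from chi-squared.
#'
#' @param fit_m1a,fit_m2a `site_model_fit` objects for the same gene.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
site_lrt <- function(fit_m1a, fit_m2a) {
  stopifnot(fit_m1a$model == "M1a", fit_m2a$model == "M2a")
  stat <- max(2 * (fit_m2a$log_likelihood - fit_m1a$log_likelihood), 0)
  tibble(statistic = stat, df = 2L,
         p_value = pchisq(stat, 2, lower.tail = FALSE))
}

#' Fit the preset nested site models
#'
#' Runs M0, M1a and M2a in sequence, warm-starting each model from the
#' previous (nested) fit, and reports the M1a-vs-M2a likelihood-ratio
#' test.
#'
#' @inheritParams fit_site_model
#' @param models Models to fit (subset of M0/M1a/M2a, in nesting order).
#' @return List: `fits` (named list of `site_model_fit`), `lrt`
#'   (M1a vs M2a tibble, when both were fit).
#' @export
fit_site_models <- function(tree, aln, models = c("M0", "M1a", "M2a"),
                            pi_method = "f3x4", n_starts = 2, seed = 1) {
  fits <- list()
  prev <- NULL
  for (m in models) {
    fits[[m]] <- fit_site_model(tree, aln, m, pi_method = pi_method,
                                n_starts = n_starts, seed = seed,
                                chain_from = prev)
    prev <- fits[[m]]
  }
  lrt <- if (all(c("M1a", "M2a") %in% names(fits))) {
    site_lrt(fits$M1a, fits$M2a)
  }
  list(fits = fits, lrt = lrt)
}

#' Positively selected sites under M2a (Naive Empirical Bayes)
#'
#' @param fit_m2a An M2a `site_model_fit`.
#' @return Tibble: `site`, `posterior`, `selected` (posterior >= 0.95).
#' @export
positive_sites <- function(fit_m2a) {
  stopifnot(fit_m2a$model == "M2a")
  p <- fit_m2a$site_posterior
  tibble(site = seq_along(p), posterior = p,
         selected = p >= fit_m2a$pos_site_threshold)
}
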