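#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mk_fit <- function(x, ...) {
  k <- length(x$states)
  if (x$model == "mk1") {
    return(tibble(term = "q", estimate = x$rates))
  }
  pairs <- expand.grid(to = x$states, from = x$states)[, 2:1]
  pairs <- pairs[pairs$from != pairs$to, ]
  tibble(term = paste0("q_", pairs$from, "->", pairs$to), estimate = x$rates)
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$log_likelihood, npar = x$npar,
         boundary = x$boundary, convergence = x$convergence)
}

#' @export
tidy.site_model_fit <- function(x, ...) {
  bind_rows(
    tibble(term = c("rho", "kappa"), estimate = c(x$rho, x$kappa)),
    tibble(term = paste0("omega", seq_along(x$omegas) - 1), estimate = x$omegas),
    if (length(x$probs) > 1)
      tibble(term = paste0("p", seq_along(x$probs) - 1), estimate = x$probs))
}

#' @export
glance.site_model_fit <- function(x, ...) {
  tibble(model = x$model, gene = x$gene, logLik = x$log_likelihood,
         npar = x$npar, convergence = x$convergence)
}

#' @export
tidy.age_regression <- function(x, ...) x$per_group

#' @export
glance.age_regression <- function(x, ...) {
  tibble(F = x$equality$F, df1 = x$equality$df1, df2 = x$equality$df2,
         p_value = x$equality$p_value)
}

#' @export
tidy.bayes_asr <- function(x, ...) x$posterior

#' @export
glance.bayes_asr <- function(x, ...) {
  tibble(support_call = x$support_call, n_chains = x$n_chains,
         min_ess = min(x$ess), ess_ok = x$ess_ok,
         n_discarded = sum(x$n_discarded))
}

#' @export
tidy.parsimony_asr <- function(x, ...) {
  select(x$node_states, "node", "label", "state", "state_set")
}

#' @export
glance.parsimony_asr <- function(x, ...) {
  tibble(total_steps = x$total_steps, root_state = x$root_state,
         root_tied = length(x$root_candidates) > 1)
}

#' @export
tidy.shift_comparison <- function(x, ...) {
  select(x$comparisons, -"shift_branches", -"sister_branches")
}

#' @export
glance.shift_comparison <- function(x, ...) x$test
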