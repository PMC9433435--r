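test_that("Fitch parsimony handles trivial and forced cases", {
  tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
  all_same <- trait_table(LETTERS[1:4], rep("hemiedaphic", 4),
                          states = lifeform_states())
  rec <- fitch_parsimony(tr, all_same)
  expect_equal(rec$total_steps, 0L)
  expect_true(all(rec$node_states$state == "hemiedaphic"))

  tt <- trait_table(LETTERS[1:4], c("hemiedaphic", "euedaphic",
                                    "hemiedaphic", "hemiedaphic"))
  rec <- fitch_parsimony(tr, tt)
  expect_equal(rec$total_steps, 1L)
  expect_equal(rec$root_state, "hemiedaphic")
  expect_equal(rec$realized_steps, rec$total_steps)
  expect_error(fitch_parsimony(tr, trait_table(LETTERS[1:3], rep("x", 3),
                                               states = c("x", "y"))),
               "untraited")
})

test_that("Fitch equals the exhaustive minimum and the resolution realises it", {
  set.seed(101)
  for (i in 1:150) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- random_test_tree(n, polytomy = i %% 3 == 0)
    states <- letters[1:k]
    tip_states <- sample(seq_len(k), n, replace = TRUE)
    tt <- trait_table(tr$phylo$tip.label, states[tip_states], states = states)
    rec <- fitch_parsimony(tr, tt)
    expect_identical(rec$total_steps,
                     as.integer(oracle_parsimony_steps(tr, tip_states, k)))
    expect_identical(rec$realized_steps, rec$total_steps)
  }
})

test_that("Fitch step counts agree with phangorn on bifurcating trees", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    tr <- random_test_tree(n)
    k <- sample(2:4, 1)
    st <- sample(letters[1:k], n, replace = TRUE)
    tt <- trait_table(tr$phylo$tip.label, st, states = letters[1:k])
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(tr$phylo$tip.label, NULL)),
                            type = "USER", levels = letters[1:k])
    expect_equal(fitch_parsimony(tr, tt)$total_steps,
                 as.integer(phangorn::parsimony(tr$phylo, dat)))
  }
})

test_that("shift events are maximal, disjoint subtrees in the derived state", {
  tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
  all_same <- trait_table(LETTERS[1:4], rep("hemi", 4), states = c("hemi", "eu"))
  rec <- fitch_parsimony(tr, all_same)
  expect_equal(nrow(count_state_shifts(rec, "hemi")), 0)

  tt <- trait_table(LETTERS[1:4], c("hemi", "eu", "hemi", "hemi"))
  ev <- count_state_shifts(fitch_parsimony(tr, tt), "hemi")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$derived_state, "eu")
  expect_equal(ev$members[[1]], "B")

  tr2 <- parse_tree("(((A:1,B:1):1,C:2):1,D:3);")
  tt2 <- trait_table(LETTERS[1:4], c("epi", "epi", "hemi", "hemi"))
  rec2 <- fitch_parsimony(tr2, tt2, prefer_state = "hemi")
  ev2 <- count_state_shifts(rec2, "hemi")
  expect_equal(nrow(ev2), 1)
  expect_setequal(ev2$members[[1]], c("A", "B"))
  expect_equal(ev2$origin, find_mrca(tr2, c("A", "B")))
  expect_error(count_state_shifts(rec2, "nonstate"), "not in state set")
})

test_that("fixture reconstruction: hemiedaphic ancestor, six derived origins", {
  tr <- example_ingroup_tree()
  tt <- example_traits()
  rec <- fitch_parsimony(tr, tt, prefer_state = "hemiedaphic")
  expect_equal(rec$root_state, "hemiedaphic")
  ev <- count_state_shifts(rec, "hemiedaphic")
  tab <- table(ev$derived_state)
  expect_equal(tab[["epiedaphic"]], 2L)
  expect_equal(tab[["euedaphic"]], 2L)
  expect_equal(tab[["aquatic"]], 1L)
  expect_equal(tab[["myrmecophilous"]], 1L)
  sy <- ev[ev$derived_state == "epiedaphic" & ev$n_members == 4, ]
  expect_equal(nrow(sy), 1)
  expect_setequal(sy$members[[1]],
                  c("Allacma_fusca", "Sminthurus_viridis",
                    "Bourletiella_arvalis", "Dicyrtomina_ornata"))
})

test_that("retention index follows (g-s)/(g-r) with the autapomorphy convention", {
  # state on A and C of ((A,B),(C,D)): two origins, maximal homoplasy
  tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
  tt <- trait_table(LETTERS[1:4], c("x", "y", "x", "y"))
  ri <- retention_index(tr, tt, "x")
  expect_equal(ri$g, 2L); expect_equal(ri$s, 2L); expect_equal(ri$r, 1L)
  expect_equal(ri$ri, 0)
  expect_true(ri$defined)
  # no homoplasy: s = r gives RI 1
  tt2 <- trait_table(LETTERS[1:4], c("x", "x", "y", "y"))
  expect_equal(retention_index(tr, tt2, "x")$ri, 1)
  # autapomorphy: g = r, ratio 0/0, reported 0 and undefined
  tt3 <- trait_table(LETTERS[1:4], c("x", "y", "y", "y"))
  ri3 <- retention_index(tr, tt3, "x")
  expect_equal(ri3$ri, 0)
  expect_false(ri3$defined)
})

test_that("Mk likelihood limits match theory", {
  tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
  tt <- trait_table(LETTERS[1:4], rep("x", 4), states = c("x", "y"))
  # q -> 0: only root-state uncertainty remains
  expect_equal(mk_log_likelihood(tr, tt, 1e-10, "mk1"), log(1 / 2),
               tolerance = 1e-6)
  # q -> infinity: tip states independent uniform
  tt2 <- trait_table(LETTERS[1:4], c("x", "y", "x", "y"))
  expect_equal(mk_log_likelihood(tr, tt2, 1e3, "mk1"), 4 * log(1 / 2),
               tolerance = 1e-4)
  # closed-form 2-state kernel on a 2-tip tree
  tr2 <- parse_tree("(A:1,B:1);")
  tt3 <- trait_table(c("A", "B"), c("x", "x"), states = c("x", "y"))
  p_same <- 1 / 2 + 1 / 2 * exp(-2 * 0.1)
  expect_equal(mk_log_likelihood(tr2, tt3, 0.1, "mk1"),
               log(0.5 * p_same^2 + 0.5 * (1 - p_same)^2), tolerance = 1e-9)
  expect_error(mk_log_likelihood(tr2, tt3, -1, "mk1"), "negative")
})

test_that("pruning equals brute-force state sums on small trees", {
  set.seed(202)
  for (i in 1:150) {
    n <- sample(3:5, 1)
    k <- sample(2:3, 1)
    tr <- random_test_tree(n, polytomy = i %% 4 == 0)
    states <- letters[1:k]
    tip_states <- sample(seq_len(k), n, replace = TRUE)
    tt <- trait_table(tr$phylo$tip.label, states[tip_states], states = states)
    model <- if (i %% 2 == 0) "mk1" else "asymm"
    rates <- if (model == "mk1") runif(1, 0.01, 2) else runif(k * (k - 1), 0.01, 2)
    Q <- collemsel:::mk_rate_matrix(rates, k, model)
    ll <- mk_log_likelihood(tr, tt, rates, model)
    oracle <- oracle_mk_likelihood(tr, tip_states, Q, rep(1 / k, k))
    expect_equal(ll, log(oracle), tolerance = 1e-9)
  }
})

test_that("marginal ancestral probabilities are proper and consistent", {
  tr <- example_ingroup_tree()
  tt <- example_traits()
  fit <- fit_mk(tr, tt, "mk1")
  expect_true(all(abs(rowSums(fit$anc_prob) - 1) < 1e-9))
  # ML root marginal agrees with the parsimony root state on the fixture
  expect_equal(names(which.max(fit$anc_prob[tr$root, ])), "hemiedaphic")
})

test_that("AsymmMk nests Mk1 and the LRT behaves", {
  tr <- random_test_tree(12)
  set.seed(33)
  tt <- trait_table(tr$phylo$tip.label,
                    sample(c("x", "y"), 12, replace = TRUE), states = c("x", "y"))
  f1 <- fit_mk(tr, tt, "mk1")
  f2 <- fit_mk(tr, tt, "asymm")
  expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-6)
  lrt <- mk_lrt(f1, f2)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)  # k = 2: 2 rates - 1
  # constant character: rate driven to the lower bound and flagged
  cc <- trait_table(tr$phylo$tip.label, rep("x", 12), states = c("x", "y"))
  fc <- fit_mk(tr, cc, "mk1")
  expect_true(fc$boundary)
})

test_that("Mk1-vs-AsymmMk LRT holds its size under the null", {
  set.seed(404)
  tr <- simulate_bd_tree(16, 1, 0, 400, seed = 404)
  n_rej <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    sim <- simulate_mk_trait(tr, 0.004, "x", c("x", "y"), seed = 7000 + r)
    if (length(unique(sim$traits$state)) < 2) next  # constant: LRT undefined
    f1 <- fit_mk(tr, sim$traits, "mk1")
    f2 <- fit_mk(tr, sim$traits, "asymm")
    if (mk_lrt(f1, f2)$p_value < 0.05) n_rej <- n_rej + 1
  }
  # binomial 95% acceptance band for alpha = 0.05 at 200 replicates
  expect_gte(n_rej / n_rep, 0.02)
  expect_lte(n_rej / n_rep, 0.09)
})

test_that("pooled Mk1 rate recovery across characters is within 30%", {
  q_true <- 0.005
  tr <- simulate_bd_tree(64, 1, 0, 400, seed = 99)
  sims <- lapply(1:100, function(i) {
    simulate_mk_trait(tr, q_true, "x", c("x", "y"), seed = 9000 + i)$traits
  })
  nll <- function(logq) {
    -sum(vapply(sims, function(tt) {
      mk_log_likelihood(tr, tt, exp(logq), "mk1")
    }, 0))
  }
  opt <- optimize(nll, log(c(1e-5, 1)))
  q_hat <- exp(opt$minimum)
  expect_gt(q_hat, q_true * 0.7)
  expect_lt(q_hat, q_true * 1.3)
})

test_that("Bayesian ASR recovers obvious signal and flags support correctly", {
  tr <- simulate_bd_tree(24, 1, 0, 200, seed = 11)
  tt <- trait_table(tr$phylo$tip.label, rep("x", 24), states = c("x", "y"))
  res <- bayes_asr(tr, tt, focal_clade = tr$phylo$tip.label,
                   n_chains = 2, n_iter = 1500, seed = 5)
  expect_gt(res$posterior$probability[res$posterior$state == "x"], 0.9)
  expect_equal(res$support_call, "x")
  expect_error(bayes_asr(tr, tt, tr$phylo$tip.label, burn_in = 1.2), "burn_in")
  expect_error(bayes_asr(tr, tt, character(0)), "empty focal clade")
})

test_that("MCMC matches exact quadrature of the hierarchical-prior posterior", {
  # k = 2 all-rates model: integrating the Exp(m), m ~ U(0, 30) hyper-prior
  # gives p(r1, r2) = exp(-(r1 + r2)/30) / (30 (r1 + r2)) in closed form,
  # so the posterior root-state probability (with the same equivocal-sample
  # rule) is computable by 2-D quadrature, independently of the sampler.
  tr <- simulate_bd_tree(8, 1, 0, 2, seed = 11)  # depth on the sampling scale
  tt <- trait_table(tr$phylo$tip.label, rep("x", 8), states = c("x", "y"))
  lg <- seq(-7, log(30), length.out = 41)
  grid <- expand.grid(l1 = lg, l2 = lg)
  w <- num <- den <- 0
  thr <- 1 / 2 + 0.02
  for (i in seq_len(nrow(grid))) {
    r1 <- exp(grid$l1[i]); r2 <- exp(grid$l2[i])
    Q <- matrix(c(-r1, r2, r1, -r2), 2, 2)
    ll <- collemsel:::mk_loglik_Q(tr, tt, Q, "stationary")
    prior <- exp(-(r1 + r2) / 30) / (30 * (r1 + r2)) * r1 * r2  # log-Jacobian
    wt <- exp(ll) * prior
    marg <- unname(collemsel:::mk_marginals(tr, tt, Q, "stationary")[tr$root, 1])
    keep <- max(marg, 1 - marg) > thr
    num <- num + wt * marg * keep
    den <- den + wt * keep
  }
  oracle <- num / den
  res <- bayes_asr(tr, tt, focal_clade = tr$phylo$tip.label,
                   n_chains = 3, n_iter = 3000, seed = 7,
                   scale_branches = FALSE)
  mcmc <- unname(res$posterior$probability[res$posterior$state == "x"])
  expect_equal(mcmc, unname(oracle), tolerance = 0.05)
})
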