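make_props <- function(df, ancestral = "hemiedaphic") {
  class(df) <- c("branch_proportions", class(df))
  attr(df, "ancestral_state") <- ancestral
  df
}

test_that("branch proportions average per-gene P and label groups", {
  tr <- parse_tree("((A:50,B:50):30,C:80);")
  tt <- trait_table(c("A", "B", "C"), c("eu", "hemi", "hemi"),
                    states = c("hemi", "eu"))
  rec <- fitch_parsimony(tr, tt, prefer_state = "hemi")
  ch <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 4),
    node = rep(c(1, 2, 3, 4), 2),
    label = rep(c("A", "B", "C", ""), 2),
    is_terminal = rep(c(TRUE, TRUE, TRUE, FALSE), 2),
    branch_length = 50, parent_age = rep(c(80, 80, 80, 80), 2),
    dN = c(3, 2, 0, 1, 3, 1, 0, 0), dS = c(1, 3, 5, 1, 2, 4, 5, 0),
    N = 200, S = 100, gene_size = 100,
    omega = NA, P = NA)
  ch$P <- ifelse(ch$dN + ch$dS > 0, ch$dN / (ch$dN + ch$dS), NA)
  pr <- branch_proportions(ch, tr, rec)
  # dN=3, dS=1 -> P=0.75 for A on g1; averaged with g2 (0.6)
  a <- pr[pr$label == "A", ]
  expect_equal(a$P, mean(c(0.75, 0.6)))
  expect_equal(a$group, "alternative")
  expect_equal(pr$group[pr$label == "B"], "ancestral")
  # gene with no changes on the internal branch is dropped from its average
  internal <- pr[pr$label == "", ]
  expect_equal(internal$P, 0.5)
  expect_equal(internal$n_genes, 1L)
  expect_equal(internal$n_genes_dropped, 1L)
  # the stated averaging rule: two genes with P 0.4 and 0.6 average to 0.5
  expect_equal(mean(c(0.4, 0.6)), 0.5)
})

test_that("paired t test matches hand computation and handles degeneracies", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, df = 2L, p_value = 1, mean_difference = 0))
  ht <- paired_t_test(c(1, 2, 4), c(2, 2, 2))
  # d = (-1, 0, 2): mean 1/3, sd = sqrt(7/3), t = (1/3)/(sqrt(7/3)/sqrt(3))
  expect_equal(ht$t, (1 / 3) / (sd(c(-1, 0, 2)) / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(ht$t, 3), 0.378)
  expect_equal(ht$df, 2L)
  zt <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(zt$t) && zt$t > 0)
  expect_equal(zt$p_value, 0)
  expect_equal(paired_t_test(rnorm(416), rnorm(416))$df, 415L)
  expect_error(paired_t_test(1, 1))
})

test_that("selection classification follows the omega thresholds", {
  expect_equal(classify_selection(c(0.2, 1, 3.2, NA)),
               c("purifying", "neutral", "diversifying", "undetermined"))
  expect_equal(classify_selection(0.96), "neutral")
  expect_equal(classify_selection(0.94), "purifying")
  expect_equal(classify_selection(1.051), "diversifying")
  expect_equal(classify_selection(0.99, tol = 0), "purifying")
})

test_that("regression against age recovers structure and tests equality", {
  # perfectly collinear points give R^2 = 1
  dat <- make_props(tibble::tibble(
    P = c(0.1, 0.2, 0.3, 0.4, 0.15, 0.25, 0.35, 0.45),
    age = rep(c(10, 20, 30, 40), 2),
    group = rep(c("ancestral", "alternative"), each = 4)))
  reg <- suppressWarnings(regression_vs_age(dat))  # perfect fit warns
  expect_equal(reg$per_group$r_squared, c(1, 1), tolerance = 1e-12)
  expect_true(all(reg$per_group$slope > 0))
  glanced <- generics::glance(reg)
  expect_s3_class(glanced, "tbl_df")
  # identical groups: equality F near 0, p near 1
  dat2 <- make_props(tibble::tibble(
    P = rep(c(0.11, 0.19, 0.32, 0.41), 2),
    age = rep(c(10, 20, 30, 40), 2),
    group = rep(c("ancestral", "alternative"), each = 4)))
  reg2 <- regression_vs_age(dat2)
  expect_lt(reg2$equality$F, 1e-20)
  expect_gt(reg2$equality$p_value, 0.999)
  expect_error(regression_vs_age(make_props(tibble::tibble(
    P = c(0.1, 0.2, 0.3), age = c(1, 2, 3),
    group = c("ancestral", "ancestral", "alternative")))), "at least 3")
})

test_that("group-equality test holds its size when groups share one model", {
  set.seed(55)
  n_rej <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    age <- runif(40, 0, 400)
    P <- 0.3 + 0.0005 * age + rnorm(40, 0, 0.05)
    dat <- make_props(tibble::tibble(P = P, age = age,
                                     group = rep(c("ancestral", "alternative"), 20)))
    if (regression_vs_age(dat)$equality$p_value < 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej / n_rep, 0.02)
  expect_lte(n_rej / n_rep, 0.09)
})

test_that("shift-vs-sister shares sum to 100 and sides are disjoint", {
  tr <- parse_tree("(((A:40,B:40):40,(C:50,D:50):30):20,E:100);")
  tt <- trait_table(LETTERS[1:5], c("eu", "eu", "hemi", "hemi", "hemi"),
                    states = c("hemi", "eu"))
  rec <- fitch_parsimony(tr, tt, prefer_state = "hemi")
  ev <- count_state_shifts(rec, "hemi")
  pr <- make_props(tibble::tibble(
    node = 1:9, label = c(LETTERS[1:5], rep("", 4)),
    is_terminal = c(rep(TRUE, 5), rep(FALSE, 4)),
    P = c(0.6, 0.7, 0.3, 0.4, 0.35, 0.5, 0.45, 0.3, 0.25),
    age = 50, group = "ancestral", state = rec$node_states$state,
    n_genes = 1, n_genes_dropped = 0), "hemi")
  sv <- shift_vs_sister(ev, pr, tr, rec)
  comp <- sv$comparisons
  expect_equal(comp$shift_share_pct + comp$sister_share_pct, rep(100, nrow(comp)))
  expect_length(intersect(comp$shift_branches[[1]], comp$sister_branches[[1]]), 0)
  # shift side of the AB clade: A, B and the AB stem
  ab_stem <- find_mrca(tr, c("A", "B"))
  expect_setequal(comp$shift_branches[[1]], c(1, 2, ab_stem))
  # equal side means give a 50/50 share and t = 0 across tied events
  pr2 <- pr
  pr2$P <- rep(0.4, 9)
  sv2 <- shift_vs_sister(ev, pr2, tr, rec)
  expect_equal(sv2$comparisons$shift_share_pct, 50)
  # single-event comparisons cannot produce a paired test
  expect_true(is.na(sv2$test$t))
})

test_that("single-taxon shifts use only the terminal branch on the shift side", {
  tr <- parse_tree("((A:60,B:60):40,C:100);")
  tt <- trait_table(c("A", "B", "C"), c("aquatic", "hemi", "hemi"),
                    states = c("hemi", "aquatic"))
  rec <- fitch_parsimony(tr, tt, prefer_state = "hemi")
  ev <- count_state_shifts(rec, "hemi")
  pr <- make_props(tibble::tibble(
    node = 1:5, label = c("A", "B", "C", "", ""),
    is_terminal = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    P = c(0.8, 0.4, 0.3, 0.2, 0.1), age = c(60, 60, 100, 100, 100),
    group = "x", state = rec$node_states$state, n_genes = 1,
    n_genes_dropped = 0), "hemi")
  sv <- shift_vs_sister(ev, pr, tr, rec)
  expect_equal(sv$comparisons$shift_branches[[1]], 1L)
  expect_equal(sv$comparisons$shift_mean_P, 0.8)
  expect_equal(sv$comparisons$sister_mean_P, 0.4)
})

test_that("nested second shifts are excluded from the sister side", {
  tr <- parse_tree("(((A:30,B:30):30,(C:40,D:40):20):40,E:100);")
  tt <- trait_table(LETTERS[1:5], c("eu", "eu", "epi", "hemi", "hemi"),
                    states = c("hemi", "eu", "epi"))
  rec <- fitch_parsimony(tr, tt, prefer_state = "hemi")
  ev <- count_state_shifts(rec, "hemi")
  ev_eu <- ev[ev$derived_state == "eu", ]
  pr <- make_props(tibble::tibble(
    node = 1:9, label = c(LETTERS[1:5], rep("", 4)),
    is_terminal = c(rep(TRUE, 5), rep(FALSE, 4)),
    P = rep(0.5, 9), age = 50, group = "x",
    state = rec$node_states$state, n_genes = 1, n_genes_dropped = 0), "hemi")
  sv <- shift_vs_sister(ev_eu, pr, tr, rec)
  sister <- sv$comparisons$sister_branches[[1]]
  # the epiedaphic tip C must not appear on the eu event's sister side
  expect_false(3 %in% sister)
  expect_true(4 %in% sister)
})
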