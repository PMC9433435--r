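code5 <- genetic_code(5)

test_that("the invertebrate mitochondrial code is bound correctly", {
  expect_equal(translate_codon("TGA", code5), "W")
  expect_equal(translate_codon("AGA", code5), "S")
  expect_equal(translate_codon("AGG", code5), "S")
  expect_equal(translate_codon("ATA", code5), "M")
  expect_equal(translate_codon("TAA", code5), "*")
  expect_equal(length(code5$sense), 62)
  expect_setequal(code5$stops, c("TAA", "TAG"))
  expect_error(translate_codon("ATN", code5), "masked")
})

test_that("ng_sites matches neighbour enumeration", {
  expect_equal(ng_sites("TTT", code5), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_sites("GGA", code5), c(s = 1, n = 2))
  # ATA is Met under table 5: only ATG at position 3 is synonymous
  expect_equal(ng_sites("ATA", code5)[["s"]], 1 / 3)
  expect_error(ng_sites("TAA", code5), "stop")
  # every sense codon: s + n = 3 under the per-position scaling
  sums <- vapply(code5$sense, function(cd) sum(ng_sites(cd, code5)), 0)
  expect_true(all(abs(sums - 3) < 1e-12))
})

test_that("pathway counts average over stop-avoiding minimal paths", {
  expect_equal(pathway_count("TTT", "TTA", code5), c(nd = 1, sd = 0))
  expect_equal(pathway_count("CTT", "CTC", code5), c(nd = 0, sd = 1))
  expect_equal(pathway_count("TTT", "GTA", code5), c(nd = 1.5, sd = 0.5))
  expect_equal(pathway_count("AAA", "AAA", code5), c(nd = 0, sd = 0))
})

test_that("pathway counting is symmetric and exact for one-step pairs", {
  pcm <- collemsel:::pathway_count_matrices(code5)
  expect_equal(pcm$ND, t(pcm$ND), tolerance = 1e-12)
  expect_equal(pcm$SD, t(pcm$SD), tolerance = 1e-12)
  one_step <- code5$pair_type != 0L
  expect_true(all(abs(pcm$ND[one_step] + pcm$SD[one_step] - 1) < 1e-12))
  # pathway totals equal the number of differing positions
  for (i in sample(62, 5)) for (j in sample(62, 5)) {
    d <- sum(strsplit(code5$sense[i], "")[[1]] != strsplit(code5$sense[j], "")[[1]])
    expect_equal(pcm$ND[i, j] + pcm$SD[i, j], d, tolerance = 1e-12)
  }
})

test_that("GY94 rate matrices satisfy detailed balance and normalisation", {
  set.seed(5)
  pi <- runif(62); pi <- pi / sum(pi)
  m <- gy94_rate_matrix(3.2, 0.4, pi, code5)
  expect_true(max(abs(rowSums(m$Q))) < 1e-10)
  flux <- pi * m$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(m$Q)), m$rate)
})

test_that("mixture likelihood with one class equals M0 at the same omega", {
  tr <- simulate_bd_tree(5, 1, 0, 200, seed = 2)
  sim <- simulate_codon_alignment(tr, 40, kappa = 2, omega = 0.5, rate = 0.002,
                                  seed = 3)
  pat <- collemsel:::codon_tip_patterns(tr, sim$aln)
  pi <- codon_frequencies(sim$aln)
  ll_m0 <- collemsel:::codon_mixture_loglik(
    collemsel:::codon_class_logliks(tr, pat, 2, 0.5, 1, 0.002, pi, code5),
    1, pat$weights)
  # two identical classes at the same omega
  ll_mix <- collemsel:::codon_mixture_loglik(
    collemsel:::codon_class_logliks(tr, pat, 2, c(0.5, 0.5), c(0.3, 0.7),
                                    0.002, pi, code5),
    c(0.3, 0.7), pat$weights)
  expect_equal(ll_mix, ll_m0, tolerance = 1e-9)
})

test_that("codon pruning equals brute-force enumeration on 3-taxon trees", {
  set.seed(77)
  for (case in 1:50) {
    t_ab <- runif(1, 20, 150); t_in <- runif(1, 10, 80); t_c <- runif(1, 20, 200)
    kappa <- runif(1, 0.5, 8); omega <- runif(1, 0.05, 3)
    pi <- runif(62, 0.5, 1.5); pi <- pi / sum(pi)
    tr <- parse_tree(sprintf("((A:%f,B:%f):%f,C:%f);", t_ab, t_ab, t_in, t_c))
    states <- matrix(sample.int(62, 12, replace = TRUE), nrow = 3)
    pat <- list(states = states - 1L, weights = rep(1, 4), pat_index = 1:4)
    ll <- collemsel:::codon_class_logliks(tr, pat, kappa, omega, 1, 1, pi, code5)
    oracle <- oracle_codon_loglik_3tax(kappa, omega, pi, t_ab, t_in, t_c,
                                       states, code5)
    expect_equal(sum(ll[1, ]), oracle, tolerance = 1e-8)
  }
})

test_that("ancestral codon reconstruction is exact on invariant sites", {
  tr <- parse_tree("((A:50,B:50):30,(C:60,D:60):20);")
  seqs <- setNames(rep("ATGGCTCTTAAA", 4), LETTERS[1:4])
  aln <- codon_alignment(seqs, code5, gene = "inv")
  rec <- reconstruct_ancestral_codons(tr, aln,
                                      params = list(kappa = 2, omega = 0.5,
                                                    rho = 0.001))
  anc <- rec$node_codons[-(1:4), ]
  expect_true(all(anc == rep(c("ATG", "GCT", "CTT", "AAA"), each = 3)))
  expect_true(all(rec$posterior[-(1:4), ] > 0.99))
})

test_that("two-taxon ancestral marginals follow the closed form", {
  tr <- parse_tree("(A:40,B:60);")
  aln <- codon_alignment(c(A = "TTT", B = "TTA"), code5, gene = "two")
  kappa <- 2; omega <- 0.5; rho <- 0.002
  pi <- rep(1 / 62, 62)
  rec <- reconstruct_ancestral_codons(tr, aln,
                                      params = list(kappa = kappa, omega = omega,
                                                    rho = rho, pi = pi))
  m <- gy94_rate_matrix(kappa, omega, pi, code5)
  P40 <- as.matrix(Matrix::expm(m$Q * 40 * rho / m$rate))
  P60 <- as.matrix(Matrix::expm(m$Q * 60 * rho / m$rate))
  iT <- match("TTT", code5$sense); iA <- match("TTA", code5$sense)
  marg <- pi * P40[, iT] * P60[, iA]
  marg <- marg / sum(marg)
  best <- which.max(marg)
  expect_equal(rec$node_codons[3, 1], code5$sense[best])
  expect_equal(rec$posterior[3, 1], max(marg), tolerance = 1e-6)
})

test_that("reconstruction recovers most true ancestral states at low divergence", {
  tr <- simulate_bd_tree(10, 1, 0, 300, seed = 21)
  sim <- simulate_codon_alignment(tr, 200, kappa = 3, omega = 0.3, rate = 5e-4,
                                  seed = 22)
  rec <- reconstruct_ancestral_codons(tr, sim$aln, n_starts = 1)
  internal <- (tr$n_tip + 1):(tr$n_tip + tr$n_node)
  acc <- mean(rec$node_codons[internal, ] == sim$truth$node_codons[internal, ])
  expect_gte(acc, 0.9)
})

test_that("branch change counting matches direct expectations", {
  tr <- parse_tree("(A:50,B:50);")
  # identical sequences: zero counts everywhere
  aln0 <- codon_alignment(c(A = "ATGGCT", B = "ATGGCT"), code5, gene = "g0")
  rec0 <- reconstruct_ancestral_codons(tr, aln0,
                                       params = list(kappa = 2, omega = 0.5,
                                                     rho = 1e-3))
  ch0 <- branch_change_table(rec0, aln0)
  expect_true(all(ch0$dN == 0 & ch0$dS == 0))
  expect_true(all(is.na(ch0$P)))
  # one Phe -> Leu difference: (1, 0) on one branch
  aln1 <- codon_alignment(c(A = "TTTGCT", B = "TTAGCT"), code5, gene = "g1")
  rec1 <- reconstruct_ancestral_codons(tr, aln1,
                                       params = list(kappa = 2, omega = 0.5,
                                                     rho = 1e-3))
  ch1 <- branch_change_table(rec1, aln1)
  expect_equal(sum(ch1$dN), 1)
  expect_equal(sum(ch1$dS), 0)
})

test_that("an omega = 0 simulation yields no nonsynonymous changes", {
  tr <- simulate_bd_tree(8, 1, 0, 300, seed = 31)
  sim <- simulate_codon_alignment(tr, 150, kappa = 3, omega = 0, rate = 0.001,
                                  seed = 32)
  expect_equal(sum(sim$truth$branch_events$nonsyn), 0)
  rec <- asr_from_truth(tr, sim$truth)
  ch <- branch_change_table(rec, sim$aln)
  expect_equal(sum(ch$dN), 0)
  expect_gt(sum(ch$dS), 0)
})

test_that("branch omega and the standardised percentage follow their formulas", {
  expect_equal(branch_omega(0, 5, 100, 50), 0)
  expect_true(is.na(branch_omega(3, 0, 100, 50)))
  expect_equal(branch_omega(6, 3, 100, 50), 1)  # equal per-site rates
  expect_error(branch_omega(1, 1, 0, 50), "positive")
  expect_equal(standardized_gene_pct(6, 100, 3), 2)
  expect_equal(standardized_gene_pct(0, 100, 3), 0)
  expect_equal(standardized_gene_pct(12, 100, 6), standardized_gene_pct(6, 100, 3))
  expect_error(standardized_gene_pct(6, 0, 3), "positive")
})

test_that("complex summaries aggregate counts before the formula", {
  tr <- simulate_bd_tree(8, 1, 0, 300, seed = 41)
  genes <- c("nad1", "cytb", "cox1", "atp6")
  sims <- lapply(seq_along(genes), function(i) {
    simulate_codon_alignment(tr, 80, kappa = 3, omega = 0.3, rate = 0.001,
                             seed = 50 + i, gene = genes[i])
  })
  recs <- lapply(sims, function(s) asr_from_truth(tr, s$truth, s$aln$gene))
  ch <- branch_change_table(recs, lapply(sims, `[[`, "aln"))
  gp <- gene_pct_summary(ch)
  cx <- complex_summary(ch)
  # one gene per complex here: complex value equals its gene value
  expect_equal(sort(cx$pct), sort(gp$pct))
  # equal omega across genes: complex percentages differ only by noise
  expect_lt(max(cx$pct) / min(cx$pct), 2)
  # unknown gene excluded with a warning
  ch2 <- ch
  ch2$gene[ch2$gene == "nad1"] <- "mystery"
  expect_warning(cx2 <- complex_summary(ch2), "mystery")
  expect_false("I" %in% cx2$complex)
})

test_that("elevated omega on atp8 puts complex V first", {
  tr <- simulate_bd_tree(8, 1, 0, 300, seed = 61)
  genes <- list(c("nad1", 0.2), c("cytb", 0.2), c("cox1", 0.2),
                c("atp6", 0.2), c("atp8", 2.5))
  sims <- lapply(seq_along(genes), function(i) {
    simulate_codon_alignment(tr, 100, kappa = 3,
                             omega = as.numeric(genes[[i]][2]), rate = 0.001,
                             seed = 70 + i, gene = genes[[i]][1])
  })
  recs <- lapply(sims, function(s) asr_from_truth(tr, s$truth, s$aln$gene))
  ch <- branch_change_table(recs, lapply(sims, `[[`, "aln"))
  cx <- complex_summary(ch)
  expect_equal(cx$complex[1], "V")
})

test_that("site-model fits order nested likelihoods and flag positive sites", {
  tr <- simulate_bd_tree(6, 1, 0, 300, seed = 81)
  set.seed(82)
  so <- ifelse(runif(120) < 0.85, 0.2, 4)  # strong positive class
  sim <- simulate_codon_alignment(tr, 120, kappa = 3, omega = 0.3, rate = 0.002,
                                  site_omegas = so, seed = 82)
  res <- fit_site_models(tr, sim$aln, n_starts = 1)
  expect_gte(res$fits$M1a$log_likelihood, res$fits$M0$log_likelihood - 1e-6)
  expect_gte(res$fits$M2a$log_likelihood, res$fits$M1a$log_likelihood - 1e-6)
  expect_equal(res$lrt$df, 2L)
  ps <- positive_sites(res$fits$M2a)
  expect_equal(nrow(ps), 120)
  expect_true(all(ps$posterior >= 0 & ps$posterior <= 1))
  # only posterior >= 0.95 is called selected
  expect_equal(ps$selected, ps$posterior >= 0.95)
})
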