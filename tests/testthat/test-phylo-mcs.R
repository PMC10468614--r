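test_that("Newick parsing preserves structure and rejects invalid trees", {
  tr <- parse_phylogeny("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr3 <- parse_phylogeny("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr3), 3L)
  d <- ape::dist.nodes(tr3)
  root <- ape::Ntip(tr3) + 1L
  expect_equal(unname(d[which(tr3$tip.label == "A"), root]), 2)

  expect_error(parse_phylogeny("(A,B);"), "branch length")
  expect_error(parse_phylogeny("(A:1,A:1);"), "duplicate")
  expect_error(parse_phylogeny("(A:1,B:-1);"), "negative")
})

test_that("replicate aggregation is the mean of log10 levels", {
  tm <- trait_matrix(data.frame(
    organ = "liver", species = rep(c("A", "B", "C"), c(2, 1, 3)),
    metabolite = "m1", replicate = c(1, 2, 1, 1, 2, 3),
    level = c(10, 1000, 1, 100, 100, 100)))
  agg <- aggregate_replicates(tm)
  got <- setNames(agg$log10_level, agg$species)
  expect_equal(got[c("A", "B", "C")], c(A = 2, B = 0, C = 2))
  expect_error(
    trait_matrix(data.frame(organ = "o", species = "A", metabolite = "m",
                            replicate = 1, level = -1)),
    "nonpositive")
})

test_that("BM fit matches closed forms on two-tip and star trees", {
  tr <- parse_phylogeny("(A:1,B:1);")
  expect_equal(fit_bm(tr, c(A = 0, B = 2))$sigma2, 1)  # (x1-x2)^2/(4t)

  st <- star_tree(4)
  y <- setNames(c(0, 0, 2, 2), st$tip.label)
  expect_equal(fit_bm(st, y)$sigma2, sum((y - mean(y))^2) / (4 * 1))

  # constant values: exact zero rate
  expect_equal(fit_bm(st, setNames(rep(3, 4), st$tip.label))$sigma2, 0)
})

test_that("BM fit agrees with an independent MVN likelihood oracle", {
  set.seed(42)
  for (i in 1:5) {
    tr <- simulate_tree(8, seed = 100 + i)
    y <- setNames(rnorm(8, sd = runif(1, 0.5, 2)), tr$tip.label)
    fit <- fit_bm(tr, y)
    orc <- oracle_bm_ml(tr, y)
    expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-4)
    expect_equal(fit$root_state, orc$mu, tolerance = 1e-4)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
    # SE-aware fit against the oracle with nonzero sampling variances
    se <- setNames(runif(8, 0.05, 0.3), tr$tip.label)
    fit_se <- fit_bm(tr, y, tip_se = se)
    orc_se <- oracle_bm_ml(tr, y, d = se[tr$tip.label]^2)
    expect_equal(fit_se$sigma2, orc_se$sigma2, tolerance = 1e-3)
  }
})

test_that("BM rate obeys shift, scale, and branch-length invariances", {
  tr <- simulate_tree(16, seed = 7)
  set.seed(1)
  y <- setNames(rnorm(16), tr$tip.label)
  s2 <- fit_bm(tr, y)$sigma2
  expect_equal(fit_bm(tr, y + 5)$sigma2, s2)
  expect_equal(fit_bm(tr, 3 * y)$sigma2, 9 * s2)
  trk <- tr; trk$edge.length <- trk$edge.length * 4
  expect_equal(fit_bm(trk, y)$sigma2, s2 / 4)
})

test_that("SE mode with zero SEs reproduces the closed-form fit", {
  tr <- simulate_tree(12, seed = 11)
  set.seed(2)
  y <- setNames(rnorm(12), tr$tip.label)
  plain <- fit_bm(tr, y)$sigma2
  se0 <- fit_bm(tr, y, tip_se = setNames(rep(0, 12), tr$tip.label))$sigma2
  expect_lt(abs(se0 - plain) / plain, 1e-6)
})

test_that("singular phylogenetic covariance fails with a message, no jitter", {
  tr <- parse_phylogeny("((A:0,B:0):1,C:1);")  # zero-length cherry ties A and B
  expect_error(fit_bm(tr, c(A = 0, B = 1, C = 2)), "singular")
})

test_that("mcs_table inverts the rate, prunes per metabolite, censors zero rates", {
  tr <- simulate_tree(8, seed = 3)
  sigma2 <- c(m_fast = 1, m_slow = 0.01)
  tm <- simulate_bm_traits(tr, sigma2, replicate_noise_sd = 0, n_reps = 1, seed = 4)
  tab <- mcs_table(tr, tm)
  expect_equal(tab$mcs, 1 / tab$sigma2)
  expect_true(all(tab$n_tips == 8L))

  # a metabolite observed in 4 species only: fit on the pruned subtree
  agg <- aggregate_replicates(tm)
  agg_sub <- agg[!(agg$metabolite == "m_fast" & agg$species %in% tr$tip.label[1:4]), ]
  tab_sub <- mcs_table(tr, agg_sub)
  expect_equal(tab_sub$n_tips[tab_sub$metabolite == "m_fast"], 4L)

  # constant metabolite -> censored record, NA score
  aggc <- agg
  aggc$log10_level[aggc$metabolite == "m_slow"] <- 1
  tabc <- mcs_table(tr, aggc)
  expect_true(tabc$censored[tabc$metabolite == "m_slow"])
  expect_true(is.na(tabc$mcs[tabc$metabolite == "m_slow"]))

  # < 2 species metabolites are skipped and reported
  agg1 <- agg[!(agg$metabolite == "m_fast" & agg$species != tr$tip.label[1L]), ]
  tab1 <- mcs_table(tr, agg1)
  expect_false("m_fast" %in% tab1$metabolite)
  expect_match(attr(tab1, "skipped"), "m_fast")
})

test_that("rate recovery separates 100x rate groups by ~100x in median", {
  tr <- simulate_tree(64, seed = 5)
  sigma2 <- c(rep(0.01, 50), rep(1, 50))
  names(sigma2) <- sprintf("met%03d", seq_along(sigma2))
  tm <- simulate_bm_traits(tr, sigma2, replicate_noise_sd = 0, n_reps = 1, seed = 6)
  tab <- mcs_table(tr, tm)
  med_slow <- median(tab$sigma2[match(names(sigma2)[1:50], tab$metabolite)])
  med_fast <- median(tab$sigma2[match(names(sigma2)[51:100], tab$metabolite)])
  ratio <- med_fast / med_slow
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
  # and the mcs ratio is its inverse
  # even-n medians average the two middle values, so only near-equality holds
  expect_equal(median(tab$mcs[51:100]) / median(tab$mcs[1:50]), 1 / ratio,
               tolerance = 1e-3)
})

test_that("clade-split scores correlate under shared rates, not under independent ones", {
  tr <- simulate_tree(32, seed = 8)
  half_a <- tr$tip.label[1:16]
  half_b <- tr$tip.label[17:32]
  sigma2 <- 10^runif_seeded(100, -2, 1, seed = 9)
  names(sigma2) <- sprintf("met%03d", 1:100)
  tm <- simulate_bm_traits(tr, sigma2, replicate_noise_sd = 0, n_reps = 1, seed = 10)
  res <- clade_split_mcs(tr, tm, half_a, half_b)
  expect_gt(res$r, 0.5)
  expect_false(res$degenerate)

  # clade-independent rates: simulate each half separately with fresh rates
  sub_a <- prune_to_tips(tr, half_a); sub_b <- prune_to_tips(tr, half_b)
  s2a <- 10^runif_seeded(100, -2, 1, seed = 11); names(s2a) <- names(sigma2)
  s2b <- 10^runif_seeded(100, -2, 1, seed = 12); names(s2b) <- names(sigma2)
  tma <- simulate_bm_traits(sub_a, s2a, replicate_noise_sd = 0, n_reps = 1, seed = 13)
  tmb <- simulate_bm_traits(sub_b, s2b, replicate_noise_sd = 0, n_reps = 1, seed = 14)
  tm0 <- trait_matrix(rbind(as.data.frame(tma), as.data.frame(tmb)))
  res0 <- clade_split_mcs(tr, tm0, half_a, half_b)
  expect_lt(abs(res0$r), 0.3)

  # constant values in both clades -> all rates censored -> degenerate
  aggd <- aggregate_replicates(tm)
  aggd$log10_level <- 0
  resd <- clade_split_mcs(tr, aggd, half_a, half_b)
  expect_true(resd$degenerate)
  expect_true(is.na(resd$r))
})

test_that("bootstrap variance partition separates metabolite signal from replicate noise", {
  tr <- simulate_tree(12, seed = 20)
  sigma2 <- 10^seq(-2, 1, length.out = 12)
  names(sigma2) <- sprintf("met%03d", 1:12)
  # noise SD = 10% of the among-species SD scale (depth-1 tree, median sigma ~ 0.56)
  tm <- simulate_bm_traits(tr, sigma2, replicate_noise_sd = 0.05, n_reps = 3, seed = 21)
  vp <- bootstrap_variance_partition(tm, tr, n_boot = 30, seed = 22)
  expect_equal(vp$between_metabolite_fraction + vp$error_fraction, 1)
  expect_lt(vp$error_fraction, 0.10)
  expect_error(bootstrap_variance_partition(tm, tr, n_boot = 1), "n_boot")

  # identical replicates within every pair: resampling cannot change scores
  tm0 <- simulate_bm_traits(tr, sigma2, replicate_noise_sd = 0, n_reps = 3, seed = 23)
  vp0 <- bootstrap_variance_partition(tm0, tr, n_boot = 5, seed = 24)
  expect_equal(vp0$error_fraction, 0, tolerance = 1e-12)
})
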