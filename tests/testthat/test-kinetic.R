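test_that("native model format round-trips value-identically and validates symbols", {
  m <- toy_kinetic_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$species, m$species)
  expect_equal(m2$boundary, m$boundary)
  expect_equal(length(m2$reactions), 8L)
  for (r in names(m$reactions)) {
    expect_identical(m2$reactions[[r]]$params, m$reactions[[r]]$params)
    expect_identical(m2$reactions[[r]]$stoich, m$reactions[[r]]$stoich)
    expect_identical(m2$reactions[[r]]$rate, m$reactions[[r]]$rate)
  }
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(
    kinetic_model(species = c(A = 1), reactions = list(
      v1 = list(stoich = c(A = -1), rate = "k * Azz", params = c(k = 1)))),
    "Azz")
  expect_error(
    kinetic_model(species = c(A = 1), reactions = list(
      v1 = list(stoich = c(B = -1), rate = "k * A", params = c(k = 1)))),
    "stoichiometry")
})

test_that("steady state solves the linear chain analytically", {
  m <- chain_model(k = 2, src = 1)
  ss <- steady_state(m)
  expect_true(ss$converged)
  expect_equal(unname(ss$concentrations["A"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(ss$fluxes["v_deg"]), 1, tolerance = 1e-8)
  # doubling consumption halves the pool but not the throughput
  m4 <- chain_model(k = 4, src = 1)
  ss4 <- steady_state(m4)
  expect_equal(unname(ss4$concentrations["A"]), 0.25, tolerance = 1e-8)
  expect_equal(unname(ss4$fluxes["v_deg"]), 1, tolerance = 1e-8)
})

test_that("an overdriven saturable sink has no steady state and fails as a value", {
  m <- kinetic_model(
    species = c(A = 1), boundary = c(X0 = 1),
    reactions = list(
      v_src = list(stoich = c(X0 = -1, A = 1), rate = "k0 * X0", params = c(k0 = 1e6)),
      v_out = list(stoich = c(A = -1), rate = "Vm * A / (Km + A)",
                   params = c(Vm = 2, Km = 1))))
  ss <- steady_state(m, t_max = 1e3)
  expect_false(ss$converged)
})

test_that("toy model converges, conserves mass, and its steady state is unique", {
  m <- toy_kinetic_model()
  ss <- steady_state(m)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  expect_equal(unname(ss$fluxes["v_in"] - ss$fluxes["vC_out"] - ss$fluxes["vD_out"]),
               0, tolerance = 1e-8)
  keys <- attr(m, "key_fluxes")
  expect_true(all(abs(ss$fluxes[keys]) > 0))
  # uniqueness from 20 random positive starts
  set.seed(30)
  ends <- replicate(20, {
    x0 <- setNames(runif(5, 0.05, 5), names(m$species))
    s <- steady_state(m, x0 = x0)
    expect_true(s$converged)
    s$concentrations
  })
  expect_lt(max(dist(t(ends))), 1e-6)
})

test_that("mutations are multiplicative log10-normal perturbations of one parameter", {
  m <- toy_kinetic_model()
  p0 <- propose_mutation(m, sigma_mut = 0.01, alpha = 0)
  expect_equal(p0$event$new, p0$event$old)
  p1 <- propose_mutation(m, sigma_mut = 0.01, alpha = 1)
  expect_equal(p1$event$new, 10 * p1$event$old)
  expect_equal(p1$model$reactions[[p1$event$reaction]]$params[[p1$event$parameter]],
               10 * p1$event$old)
  # distributional check of alpha draws
  set.seed(31)
  draws <- replicate(20000, propose_mutation(m, sigma_mut = 0.01)$event$alpha)
  ks <- ks.test(draws, "pnorm", 0, 0.01)
  expect_gt(ks$p.value, 0.01)
  # reactions chosen uniformly: each of the 8 reactions gets ~1/8 of proposals
  set.seed(32)
  rids <- replicate(4000, propose_mutation(m, 0.01)$event$reaction)
  expect_gt(chisq.test(table(rids))$p.value, 0.001)
})

test_that("selection distance reproduces closed-form cases", {
  m <- toy_kinetic_model()
  wt <- steady_state(m)
  keys <- attr(m, "key_fluxes")
  expect_equal(selection_distance(wt, wt, keys), 0)
  mut <- wt
  mut$fluxes[keys[1L]] <- 2 * wt$fluxes[keys[1L]]
  expect_equal(selection_distance(mut, wt, keys), 1)
  mut2 <- wt
  mut2$fluxes[keys] <- 1.1 * wt$fluxes[keys]
  expect_equal(selection_distance(mut2, wt, keys), sqrt(0.02))
  bad <- wt; bad$fluxes[keys[1L]] <- 0
  expect_error(selection_distance(wt, bad, keys), "zero")
})

test_that("drift accepts everything, selection never exceeds omega, near-zero omega freezes", {
  m <- toy_kinetic_model()
  keys <- attr(m, "key_fluxes")
  drift <- evolve(m, keys, evolution_config(omega = Inf, sigma_mut = 1e-2,
                                            iterations = 100, seed = 40))
  expect_true(all(drift$accepted))

  sel <- evolve(m, keys, evolution_config(omega = 1e-4, sigma_mut = 1e-2,
                                          iterations = 150, seed = 41))
  expect_true(all(sel$z[sel$accepted] < 1e-4))
  expect_true(any(!sel$accepted))
  # state only changes at accepted iterations
  ch <- c(TRUE, rowSums(abs(diff(sel$concentrations))) > 0)
  expect_true(all(!ch[-1] | sel$accepted[-1]))

  frozen <- evolve(m, keys, evolution_config(omega = 1e-12, sigma_mut = 1e-2,
                                             iterations = 100, seed = 42))
  wt <- frozen$wildtype$concentrations
  rel <- abs(sweep(frozen$concentrations, 2, wt) / rep(wt, each = 100))
  # metabolites on the key paths are frozen; D sits downstream of both key
  # fluxes, so mutations of its own export kinetics are exactly neutral
  # (z = 0) and D may drift even at omega -> 0
  expect_lt(max(rel[, c("A", "B", "C", "ATP")]), 1e-3)
})

test_that("evolution runs are bit-reproducible under a fixed seed", {
  m <- toy_kinetic_model()
  keys <- attr(m, "key_fluxes")
  cfg <- evolution_config(omega = 1e-4, sigma_mut = 1e-2, iterations = 60, seed = 43)
  t1 <- evolve(m, keys, cfg)
  t2 <- evolve(m, keys, cfg)
  expect_identical(t1$concentrations, t2$concentrations)
  expect_identical(t1$accepted, t2$accepted)
  expect_identical(t1$z, t2$z)
})

test_that("in-silico scores follow the trajectory-variance definition", {
  m <- toy_kinetic_model()
  keys <- attr(m, "key_fluxes")
  traj <- evolve(m, keys, evolution_config(omega = Inf, sigma_mut = 1e-2,
                                           iterations = 50, seed = 44))
  sc <- insilico_mcs(traj)
  x0 <- traj$wildtype$concentrations
  for (i in seq_along(x0)) {
    er_oracle <- var(traj$concentrations[, i] / x0[i]) / 50
    expect_equal(sc$er[i], er_oracle)
    if (er_oracle > 0) expect_equal(sc$score[i], 1 / er_oracle)
  }
  # hand series: ratios (1.0, 1.1, 0.9) -> ER = 0.01/3, score = 300
  traj_h <- traj
  traj_h$concentrations <- traj$concentrations[1:3, ]
  traj_h$concentrations[, "A"] <- x0["A"] * c(1, 1.1, 0.9)
  sc_h <- insilico_mcs(traj_h)
  expect_equal(sc_h$er[sc_h$metabolite == "A"], 0.01 / 3)
  expect_equal(sc_h$score[sc_h$metabolite == "A"], 300)
  # constant trajectory -> ER 0, flagged
  traj_c <- traj
  traj_c$concentrations <- matrix(rep(x0, each = 10), 10,
                                  dimnames = list(NULL, names(x0)))
  sc_c <- insilico_mcs(traj_c)
  expect_true(all(sc_c$excluded))
  expect_true(all(is.na(sc_c$score)))
  # named exclusions are honored
  sc_e <- insilico_mcs(traj, exclude = "ATP")
  expect_true(sc_e$excluded[sc_e$metabolite == "ATP"])
})

test_that("fitness coupling: decoupled branch anticorrelates, bounds hold, halves agree", {
  m <- toy_with_decoupled_branch()
  keys <- attr(toy_kinetic_model(), "key_fluxes")
  ens <- mutant_ensemble(m, n_mut = 600, sigma_mut = 1e-2, seed = 50)
  cp <- fitness_coupling(ens, keys)
  expect_true(all(cp$coupling >= -1 & cp$coupling <= 1, na.rm = TRUE))
  # with absolute-change ranks, a metabolite that responds only to its own
  # branch's mutations sits at the top of |dX| ranks exactly when the key
  # fluxes sit at the bottom of theirs: its coupling is structurally
  # negative, never near the positive couplings of the key-path metabolites
  expect_lt(cp$coupling["E"], -0.1)
  # main-pathway metabolites are clearly positively coupled
  expect_gt(max(cp$coupling[c("A", "B", "C")]), 0.5)
  expect_gt(min(cp$coupling[c("A", "B", "C")]) - cp$coupling["E"], 0.3)
  # keys = all reactions still yields couplings within [-1, 1]
  cp_all <- fitness_coupling(ens, names(m$reactions))
  expect_true(all(cp_all$coupling >= -1 & cp_all$coupling <= 1))
  # reproducibility across disjoint half-ensembles
  half <- function(idx) {
    e <- ens
    e$dflux <- ens$dflux[idx, , drop = FALSE]
    e$dconc <- ens$dconc[idx, , drop = FALSE]
    fitness_coupling(e, keys)$coupling
  }
  c1 <- half(1:300); c2 <- half(301:600)
  expect_lt(max(abs(c1 - c2)), 0.2)
})

test_that("a strictly monotone metabolite-flux relation gives coupling exactly 1", {
  # every mutation hits the single source parameter (the sink has none), so
  # A* = k0/2 and flux = k0 move in lockstep: |dA/A0| is strictly monotone in
  # |dv/v0| across the whole ensemble
  m <- kinetic_model(
    species = c(A = 1), boundary = c(X0 = 1),
    reactions = list(
      v_src = list(stoich = c(X0 = -1, A = 1), rate = "k0 * X0", params = c(k0 = 1)),
      v_out = list(stoich = c(A = -1), rate = "2 * A", params = NULL)))
  ens <- mutant_ensemble(m, n_mut = 200, sigma_mut = 5e-3, seed = 51)
  # verify the monotone premise on the ensemble itself, then the rank identity
  ord <- order(ens$dflux[, "v_src"])
  expect_true(all(diff(ens$dconc[ord, "A"]) >= -1e-12))
  cp <- fitness_coupling(ens, "v_src")
  expect_equal(unname(cp$coupling["A"]), 1, tolerance = 1e-9)
})

test_that("essentiality knockdowns zero the key flux on the carrying path only", {
  m <- toy_kinetic_model()
  keys <- attr(m, "key_fluxes")
  ess <- reaction_essentiality(m, keys, knockdown = 1e-5)
  # the unique C export carries key flux 1: knocking it down must zero it
  expect_true(isTRUE(ess$reaction_essential[["vC_out"]]))
  # the B -> D side branch is off both key paths
  expect_false(ess$reaction_essential[["vBD"]])
  # the D export has no steady state when knocked down (D accumulates):
  # reported as non-evaluable, not as a call either way
  expect_true(is.na(ess$reaction_essential[["vD_out"]]))
  expect_true(is.na(ess$metabolite_essential[["D"]]))
  # metabolites touching an essential reaction inherit the flag
  expect_true(ess$metabolite_essential[["C"]])
  # knockdown factor 1: nothing essential
  ess1 <- reaction_essentiality(m, keys, knockdown = 1)
  expect_false(any(ess1$reaction_essential, na.rm = TRUE))
})

test_that("random key-flux scan is consistent with the direct computation", {
  m <- toy_kinetic_model()
  keys <- attr(m, "key_fluxes")
  ens <- mutant_ensemble(m, n_mut = 400, sigma_mut = 1e-2, seed = 52)
  scan <- random_keyflux_scan(m, keys, n_combos = 200, ensemble = ens,
                              config = evolution_config(seed = 52))
  # designated-set statistic equals the direct coupling computation
  cp <- fitness_coupling(ens, keys)
  abund <- ens$wildtype$concentrations[names(cp$coupling)]
  rho_direct <- cor(abund, cp$coupling, method = "spearman")
  expect_equal(scan$designated_rho, rho_direct)
  expect_true(scan$p_coupling > 0 && scan$p_coupling <= 1)
  expect_length(scan$null_coupling_rho, 200)
  expect_error(random_keyflux_scan(m, keys, n_combos = 0, ensemble = ens), "n_combos")
})
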