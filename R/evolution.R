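#' Configuration for an evolution simulation
#'
#' @param omega Selection threshold on the key-flux deviation z; \code{Inf}
#'   means pure genetic drift (every steady-state-reaching mutant is
#'   accepted). Default 1e-4.
#' @param sigma_mut Mutation size: SD of the log10-normal factor applied to
#'   a kinetic parameter. Default 1e-2.
#' @param iterations Number of MCMC iterations T. Default 10000.
#' @param seed Master RNG seed; per-iteration child seeds are derived from
#'   it so runs are bit-reproducible.
#' @param resample_budget Maximum consecutive no-steady-state proposals
#'   within one iteration before the run aborts. Default 1000.
#' @return A list of class \code{evolution_config}.
#' @export
evolution_config <- function(omega = 1e-4, sigma_mut = 1e-2, iterations = 10000,
                             seed = 1, resample_budget = 1000) {
  stopifnot(omega > 0, sigma_mut > 0, iterations >= 1)
  structure(list(omega = omega, sigma_mut = sigma_mut, iterations = iterations,
                 seed = seed, resample_budget = resample_budget),
            class = "evolution_config")
}

#' Propose a single mutation to a kinetic parameter
#'
#' Picks a reaction uniformly at random (resampling reactions with no
#' parameters), then one of its parameters uniformly, and multiplies it by
#' \eqn{10^\alpha} with \eqn{\alpha \sim N(0, \sigma_{mut}^2)}. Uses the
#' current RNG state.
#'
#' @param model A \code{kinetic_model}.
#' @param sigma_mut Mutation SD on the log10 scale.
#' @param alpha Optional forced value of \eqn{\alpha} (for testing).
#' @return List with \code{model} (mutated copy) and \code{event}
#'   (\code{reaction}, \code{parameter}, \code{old}, \code{factor},
#'   \code{new}, \code{alpha}).
#' @export
propose_mutation <- function(model, sigma_mut, alpha = NULL) {
  has_par <- vapply(model$reactions, function(r) length(r$params) > 0L, TRUE)
  if (!any(has_par)) stop("model has no kinetic parameters", call. = FALSE)
  repeat {
    rid <- names(model$reactions)[sample.int(length(model$reactions), 1L)]
    if (length(model$reactions[[rid]]$params)) break
  }
  pn <- names(model$reactions[[rid]]$params)
  pid <- pn[sample.int(length(pn), 1L)]
  if (is.null(alpha)) alpha <- stats::rnorm(1L, 0, sigma_mut)
  old <- model$reactions[[rid]]$params[[pid]]
  new <- old * 10^alpha
  model$reactions[[rid]]$params[[pid]] <- new
  list(model = model,
       event = list(reaction = rid, parameter = pid, old = old,
                    factor = 10^alpha, new = new, alpha = alpha))
}

#' Selection distance between mutant and wild-type steady states
#'
#' The MOMA-like fitness proxy: the Euclidean norm of the key fluxes'
#' relative deviations from the wild type,
#' \eqn{z = \lVert (\nu - \nu_0)/\nu_0 \rVert_2}, element-wise division over
#' the key set only.
#'
#' @param mutant,wildtype \code{steady_state} objects (both converged).
#' @param keys Character vector of key reaction ids.
#' @return The scalar z.
#' @export
selection_distance <- function(mutant, wildtype, keys) {
  stopifnot(inherits(mutant, "steady_state"), inherits(wildtype, "steady_state"))
  if (!mutant$converged || !wildtype$converged) {
    stop("selection distance needs two converged steady states", call. = FALSE)
  }
  v0 <- wildtype$fluxes[keys]
  if (anyNA(v0)) stop("unknown key flux id", call. = FALSE)
  if (any(v0 == 0)) {
    stop("wild-type key flux is zero (model misconfiguration): ",
         paste(keys[v0 == 0], collapse = ", "), call. = FALSE)
  }
  v <- mutant$fluxes[keys]
  sqrt(sum(((v - v0) / v0)^2))
}

#' MCMC evolution of a kinetic model under drift or stabilizing selection
#'
#' Starting from the wild-type model, each iteration proposes one kinetic
#' parameter mutation (cumulative: parameters mutate from their current
#' evolved values), computes the mutant steady state (no-steady-state
#' proposals are resampled within the iteration), computes the key-flux
#' deviation z from the wild type, and accepts iff \code{z < omega}
#' (\code{omega = Inf}: drift, every steady-state-reaching mutant accepted).
#' Rejected proposals consume the iteration with the state unchanged; the
#' current concentration vector is recorded at every iteration.
#'
#' @param model A \code{kinetic_model} whose wild type must reach a steady
#'   state.
#' @param keys Character vector of key flux (reaction) ids.
#' @param config An [evolution_config()].
#' @return An object of class \code{trajectory}: \code{concentrations}
#'   (iterations x species matrix), \code{accepted} (logical), \code{z}
#'   (proposal z per iteration, NA if never computed), \code{n_resampled},
#'   \code{n_rejected}, \code{wildtype} (its \code{steady_state}),
#'   \code{final_model}, \code{config}, \code{keys}.
#' @export
evolve <- function(model, keys, config) {
  stopifnot(inherits(config, "evolution_config"))
  missing_keys <- setdiff(keys, names(model$reactions))
  if (length(missing_keys)) {
    stop("key fluxes not in model: ", paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  wt <- steady_state(model)
  if (!wt$converged) stop("wild-type model does not reach a steady state", call. = FALSE)

  sp <- names(model$species)
  T_ <- config$iterations
  conc <- matrix(NA_real_, T_, length(sp), dimnames = list(NULL, sp))
  accepted <- logical(T_)
  zs <- rep(NA_real_, T_)
  n_resampled <- 0L
  n_rejected <- 0L

  cur_model <- model
  cur_conc <- wt$concentrations

  for (t_ in seq_len(T_)) {
    set.seed(child_seed(config$seed, t_))
    tries <- 0L
    repeat {
      prop <- propose_mutation(cur_model, config$sigma_mut)
      ss <- steady_state(prop$model, x0 = cur_conc)
      if (ss$converged) break
      tries <- tries + 1L
      n_resampled <- n_resampled + 1L
      if (tries >= config$resample_budget) {
        stop(sprintf("resample budget exhausted at iteration %d (%d consecutive no-steady-state proposals)",
                     t_, tries), call. = FALSE)
      }
    }
    z <- selection_distance(ss, wt, keys)
    zs[t_] <- z
    if (z < config$omega) {
      cur_model <- prop$model
      cur_conc <- ss$concentrations
      accepted[t_] <- TRUE
    } else {
      n_rejected <- n_rejected + 1L
    }
    conc[t_, ] <- cur_conc
  }
  structure(list(concentrations = conc, accepted = accepted, z = zs,
                 n_resampled = n_resampled, n_rejected = n_rejected,
                 wildtype = wt, final_model = cur_model, config = config,
                 keys = keys),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: T = %d, accepted %.1f%%, resampled %d, omega = %g\n",
              length(x$accepted), 100 * mean(x$accepted), x$n_resampled,
              x$config$omega))
  invisible(x)
}

#' In-silico conservation scores from an evolution trajectory
#'
#' Per metabolite, the evolution rate is the sample variance (denominator
#' n - 1) of the level ratios to wild type over the iterations, divided by
#' the number of iterations: \eqn{ER = var(X_t/X_0)/T}; the conservation
#' score is \eqn{1/ER}. Metabolites with zero variance, a zero wild-type
#' level, or named in \code{exclude} are flagged and get \code{NA} scores.
#'
#' @param traj A \code{trajectory}.
#' @param wildtype Optional \code{steady_state} (defaults to the
#'   trajectory's own wild type).
#' @param exclude Metabolite ids to exclude (e.g. levels with underestimated
#'   variability in a specific model).
#' @return Data.frame \code{metabolite, er, score, excluded}.
#' @export
insilico_mcs <- function(traj, wildtype = NULL, exclude = character()) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(wildtype)) wildtype <- traj$wildtype
  T_ <- nrow(traj$concentrations)
  if (T_ < 2L) stop("need T >= 2 iterations", call. = FALSE)
  x0 <- wildtype$concentrations[colnames(traj$concentrations)]
  out <- data.frame(metabolite = colnames(traj$concentrations),
                    er = NA_real_, score = NA_real_,
                    excluded = colnames(traj$concentrations) %in% exclude,
                    stringsAsFactors = FALSE)
  for (i in seq_along(x0)) {
    if (x0[i] == 0) { out$excluded[i] <- TRUE; next }
    er <- stats::var(traj$concentrations[, i] / x0[i]) / T_
    out$er[i] <- er
    if (er > 0 && !out$excluded[i]) out$score[i] <- 1 / er
    if (er == 0) out$excluded[i] <- TRUE
  }
  out
}

#' Single-mutation ensemble of the wild-type model
#'
#' Applies \code{n_mut} independent single mutations to the wild type
#' (non-converging mutants resampled until \code{n_mut} valid ones) and
#' records the absolute relative changes of every flux and every metabolite
#' level. This ensemble underlies [fitness_coupling()] and
#' [random_keyflux_scan()].
#'
#' @param model A \code{kinetic_model}.
#' @param n_mut Number of valid mutants.
#' @param sigma_mut Mutation SD (log10 scale).
#' @param seed RNG seed.
#' @return List of class \code{mutant_ensemble}: \code{dflux}, \code{dconc}
#'   (n_mut x reactions / species matrices of |relative change|),
#'   \code{wildtype}, \code{n_failed}, \code{excluded_metabolites}
#'   (wild-type level zero).
#' @export
mutant_ensemble <- function(model, n_mut = 10000, sigma_mut = 1e-2, seed = 1) {
  wt <- steady_state(model)
  if (!wt$converged) stop("wild-type model does not reach a steady state", call. = FALSE)
  rids <- names(model$reactions)
  sp <- names(model$species)
  x0 <- wt$concentrations
  v0 <- wt$fluxes
  zero_x <- sp[x0 == 0]
  if (length(zero_x)) {
    warning("excluding metabolites with zero wild-type level: ",
            paste(zero_x, collapse = ", "))
  }
  dflux <- matrix(NA_real_, n_mut, length(rids), dimnames = list(NULL, rids))
  dconc <- matrix(NA_real_, n_mut, length(sp), dimnames = list(NULL, sp))
  n_failed <- 0L
  for (m in seq_len(n_mut)) {
    set.seed(child_seed(seed, m))
    repeat {
      prop <- propose_mutation(model, sigma_mut)
      ss <- steady_state(prop$model, x0 = x0)
      if (ss$converged) break
      n_failed <- n_failed + 1L
      if (n_failed > 100L * n_mut) stop("too many non-converging mutants", call. = FALSE)
    }
    dflux[m, ] <- abs((ss$fluxes - v0) / ifelse(v0 == 0, NA, v0))
    dconc[m, ] <- abs((ss$concentrations - x0) / ifelse(x0 == 0, NA, x0))
  }
  structure(list(dflux = dflux, dconc = dconc, wildtype = wt,
                 n_failed = n_failed, excluded_metabolites = zero_x),
            class = "mutant_ensemble")
}

#' Fitness coupling of metabolites to the key fluxes
#'
#' For each (key flux, metabolite) pair, the Spearman correlation across a
#' single-mutation ensemble between the absolute relative flux change and
#' the absolute relative level change; a metabolite's coupling is the mean
#' of its correlations over the key set. Ties get average ranks.
#'
#' @param model A \code{kinetic_model}, or a precomputed
#'   [mutant_ensemble()].
#' @param keys Key flux ids.
#' @param n_mut,sigma_mut,seed Passed to [mutant_ensemble()] when
#'   \code{model} is a model.
#' @return List of class \code{coupling_record}: \code{coupling} (named
#'   vector over metabolites), \code{per_key} (keys x metabolites Spearman
#'   matrix), \code{n_mut}, \code{excluded}.
#' @export
fitness_coupling <- function(model, keys, n_mut = 10000, sigma_mut = 1e-2, seed = 1) {
  ens <- if (inherits(model, "mutant_ensemble")) model
         else mutant_ensemble(model, n_mut = n_mut, sigma_mut = sigma_mut, seed = seed)
  missing_keys <- setdiff(keys, colnames(ens$dflux))
  if (length(missing_keys)) stop("unknown key flux: ", paste(missing_keys, collapse = ", "),
                                 call. = FALSE)
  mets <- setdiff(colnames(ens$dconc), ens$excluded_metabolites)
  # metabolites that never respond to any mutation have an undefined rank
  # correlation; they get NA couplings (mirrors the removal of
  # mutation-insensitive metabolites from the modeling analyses)
  zero_var <- mets[apply(ens$dconc[, mets, drop = FALSE], 2L, stats::sd) == 0]
  per_key <- suppressWarnings(
    stats::cor(ens$dflux[, keys, drop = FALSE],
               ens$dconc[, mets, drop = FALSE], method = "spearman"))
  coupling <- colMeans(per_key)
  structure(list(coupling = coupling, per_key = per_key,
                 n_mut = nrow(ens$dflux), excluded = ens$excluded_metabolites,
                 zero_variance = zero_var),
            class = "coupling_record")
}

#' In-silico reaction essentiality by near-complete knockdown
#'
#' Each reaction's rate law is multiplied by a small knockdown factor, the
#' steady state recomputed, and the reaction called essential when at least
#' one key flux drops to (numerically) zero, i.e. below
#' \code{zero_tol} times its wild-type magnitude. Metabolites touching at
#' least one essential reaction (nonzero stoichiometry) are flagged.
#' Reactions whose knocked-down model fails to reach a steady state are
#' non-evaluable (\code{NA}), as are metabolites whose essential status
#' depends only on non-evaluable reactions.
#'
#' @param model A \code{kinetic_model}.
#' @param keys Key flux ids.
#' @param knockdown Rate multiplier (default 1e-5, i.e. 0.001%).
#' @param zero_tol Relative threshold for "dropped to zero" (default 1e-4;
#'   must exceed \code{knockdown}, since the knocked-down reaction's own flux
#'   can only fall to about \code{knockdown} times wild type).
#' @return List: \code{reaction_essential} (named logical, NA =
#'   non-evaluable), \code{metabolite_essential} (named logical over
#'   variable species), \code{key_flux_drops} (reactions x keys matrix of
#'   |v|/|v0|).
#' @export
reaction_essentiality <- function(model, keys, knockdown = 1e-5, zero_tol = 1e-4) {
  wt <- steady_state(model)
  if (!wt$converged) stop("wild-type model does not reach a steady state", call. = FALSE)
  v0 <- wt$fluxes[keys]
  if (any(v0 == 0)) stop("wild-type key flux is zero", call. = FALSE)
  rids <- names(model$reactions)
  ess <- stats::setNames(rep(NA, length(rids)), rids)
  drops <- matrix(NA_real_, length(rids), length(keys), dimnames = list(rids, keys))
  for (r in rids) {
    kd <- model
    kd$reactions[[r]]$rate <- sprintf("(%s) * %.17g", kd$reactions[[r]]$rate, knockdown)
    ss <- steady_state(kd, x0 = wt$concentrations)
    if (!ss$converged) next
    rel <- abs(ss$fluxes[keys]) / abs(v0)
    drops[r, ] <- rel
    ess[r] <- any(rel < zero_tol)
  }
  sp <- names(model$species)
  met_ess <- stats::setNames(rep(FALSE, length(sp)), sp)
  met_na <- stats::setNames(rep(FALSE, length(sp)), sp)
  for (r in rids) {
    touched <- intersect(names(model$reactions[[r]]$stoich), sp)
    if (isTRUE(ess[r])) met_ess[touched] <- TRUE
    if (is.na(ess[r])) met_na[touched] <- TRUE
  }
  met_ess[met_na & !met_ess] <- NA
  list(reaction_essential = ess, metabolite_essential = met_ess,
       key_flux_drops = drops)
}

#' Null scan over random key-flux combinations
#'
#' Recomputes metabolite fitness couplings for random key-flux sets (sizes
#' uniform in 1..4, fluxes sampled without replacement) from one precomputed
#' single-mutation ensemble, and per combination the Spearman correlation
#' between wild-type metabolite abundances and coupling. Optionally runs one
#' stabilizing-selection simulation for a subset of combinations and
#' correlates abundance with the in-silico conservation score. Returns the
#' null distributions and the empirical one-sided p of the designated key
#' set.
#'
#' @param model A \code{kinetic_model}.
#' @param keys The designated key set.
#' @param abundances Named vector of wild-type metabolite levels (defaults
#'   to the wild-type steady state).
#' @param n_combos Random combinations for the coupling null.
#' @param n_sim_combos Combinations that additionally get one selection
#'   simulation (expensive; default 0).
#' @param config An [evolution_config()] used for the simulations and the
#'   ensemble (sigma_mut, seed).
#' @param ensemble Optional precomputed [mutant_ensemble()].
#' @param n_mut Ensemble size when none is supplied.
#' @return List: \code{null_coupling_rho} (length n_combos),
#'   \code{designated_rho}, \code{p_coupling} (one-sided, +1 smoothed),
#'   \code{null_sim_rho} (length n_sim_combos, NULL if 0), \code{combos}.
#' @export
random_keyflux_scan <- function(model, keys, abundances = NULL, n_combos = 10000,
                                n_sim_combos = 0, config = evolution_config(),
                                ensemble = NULL, n_mut = 2000) {
  if (n_combos < 1) stop("n_combos must be >= 1", call. = FALSE)
  if (is.null(ensemble)) {
    ensemble <- mutant_ensemble(model, n_mut = n_mut, sigma_mut = config$sigma_mut,
                                seed = config$seed)
  }
  mets <- setdiff(colnames(ensemble$dconc), ensemble$excluded_metabolites)
  if (is.null(abundances)) abundances <- ensemble$wildtype$concentrations
  abund <- abundances[mets]
  # full flux x metabolite Spearman matrix once; any combo's coupling is a row mean
  full_cor <- stats::cor(ensemble$dflux, ensemble$dconc[, mets, drop = FALSE],
                         method = "spearman")
  rho_of <- function(set) {
    coup <- colMeans(full_cor[set, , drop = FALSE])
    stats::cor(abund, coup, method = "spearman")
  }
  rids <- colnames(ensemble$dflux)
  set.seed(child_seed(config$seed, 777))
  combos <- replicate(n_combos, {
    k <- sample.int(4L, 1L)
    sample(rids, min(k, length(rids)))
  }, simplify = FALSE)
  null_rho <- vapply(combos, rho_of, 1.0)
  if (stats::sd(null_rho) == 0) {
    warning("degenerate null: all combinations give the same statistic")
  }
  obs <- rho_of(keys)
  p <- (1 + sum(null_rho >= obs)) / (n_combos + 1)

  null_sim_rho <- NULL
  if (n_sim_combos > 0) {
    null_sim_rho <- rep(NA_real_, n_sim_combos)
    for (i in seq_len(n_sim_combos)) {
      cmb <- combos[[i]]
      cfg <- evolution_config(omega = config$omega, sigma_mut = config$sigma_mut,
                              iterations = config$iterations,
                              seed = child_seed(config$seed, 9000 + i))
      traj <- evolve(model, cmb, cfg)
      sc <- insilico_mcs(traj)
      ok <- !sc$excluded & is.finite(sc$score) & sc$metabolite %in% mets
      null_sim_rho[i] <- stats::cor(abundances[sc$metabolite[ok]], sc$score[ok],
                                    method = "spearman")
    }
  }
  list(null_coupling_rho = null_rho, designated_rho = obs, p_coupling = p,
       null_sim_rho = null_sim_rho, combos = combos)
}
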