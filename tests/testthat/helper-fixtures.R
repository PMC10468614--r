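# Shared fixtures and independent oracles, built in code at test time.

runif_seeded <- function(n, min, max, seed) {
  set.seed(seed)
  stats::runif(n, min, max)
}

# star tree with n tips of branch length t
star_tree <- function(n, t = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(t, n)
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr
}

# Independent BM ML oracle: direct numeric maximization of the multivariate
# normal log-likelihood over (mu, log sigma2), using determinant/solve --
# shares no code with the package's chol-based GLS profile.
oracle_bm_ml <- function(tree, y, d = NULL) {
  C <- ape::vcv(ape::keep.tip(tree, names(y)))
  y <- y[rownames(C)]
  n <- length(y)
  if (is.null(d)) d <- rep(0, n)
  nll <- function(par) {
    V <- exp(par[2L]) * C
    diag(V) <- diag(V) + d
    r <- y - par[1L]
    as.numeric(0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                        t(r) %*% solve(V, r)))
  }
  o <- stats::optim(c(mean(y), log(stats::var(y))), nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  list(mu = o$par[1L], sigma2 = exp(o$par[2L]), loglik = -o$value)
}

# two-reaction linear chain: source -> A -> sink, consumption k*A
chain_model <- function(k = 2, src = 1) {
  kinetic_model(
    name = "chain",
    species = c(A = 1),
    boundary = c(X0 = 1),
    reactions = list(
      v_src = list(stoich = c(X0 = -1, A = 1), rate = "k0 * X0",
                   params = c(k0 = src)),
      v_deg = list(stoich = c(A = -1), rate = "k1 * A", params = c(k1 = k))
    ))
}

# toy model plus an independent branch fed by its own boundary source;
# E is decoupled from the main-pathway key fluxes
toy_with_decoupled_branch <- function() {
  m <- toy_kinetic_model()
  m$species <- c(m$species, E = 1)
  m$boundary <- c(m$boundary, XE = 1)
  m$reactions$vE_in <- list(stoich = c(XE = -1, E = 1), rate = "ke_in * XE",
                            params = c(ke_in = 0.5))
  m$reactions$vE_out <- list(stoich = c(E = -1), rate = "ke_out * E",
                             params = c(ke_out = 1))
  kinetic_model(m$species, m$boundary, m$reactions, name = "toy_plus_branch")
}

# small 4-organ MCS table with exactly known scores
mcs_df <- function(scores) {
  # scores: matrix metabolite x organ of MCS values
  do.call(rbind, lapply(colnames(scores), function(org) {
    data.frame(metabolite = rownames(scores), organ = org,
               sigma2 = 1 / scores[, org], mcs = scores[, org],
               n_tips = 10L, censored = FALSE, stringsAsFactors = FALSE)
  }))
}
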