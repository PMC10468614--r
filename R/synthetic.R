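#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with the requested number of tips, rescaled so the
#' root-to-tip depth equals \code{depth} (default 1 time unit); rates are
#' then in units of trait variance per tree depth.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate of the Yule process.
#' @param seed RNG seed.
#' @param depth Root-to-tip depth after rescaling.
#' @return A \code{phylo} object, tips labeled \code{sp01, sp02, ...}.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1, depth = 1) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  h <- max(ape::node.depth.edgelength(tr)[seq_len(n_species)])
  tr$edge.length <- tr$edge.length * depth / h
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate Brownian-motion traits with replicate noise
#'
#' Evolves each metabolite's log10 level along the tree under Brownian
#' motion with its own rate (root value 0), optionally adds a constant shift
#' to all tips of a clade (emulating a lineage-specific shift in selective
#' pressure), then draws replicate measurements with Gaussian noise on the
#' log10 scale and exports linear-scale levels \code{10^value}.
#'
#' @param tree A \code{phylo} object.
#' @param sigma2 Named (or unnamed) numeric vector of per-metabolite BM
#'   rates.
#' @param replicate_noise_sd Replicate noise SD on the log10 scale (default
#'   0.1).
#' @param n_reps Replicates per (species, metabolite) (default 3).
#' @param shift Optional list \code{(tips = character, magnitude = numeric)}:
#'   constant added to the log10 value of those tips, every metabolite.
#' @param seed RNG seed.
#' @param organ Organ label for the output (default "organ1").
#' @return A \code{trait_matrix}; \code{attr(, "true_values")} holds the
#'   noiseless species x metabolite log10 matrix.
#' @export
simulate_bm_traits <- function(tree, sigma2, replicate_noise_sd = 0.1,
                               n_reps = 3, shift = NULL, seed = 1,
                               organ = "organ1") {
  validate_phylogeny(tree)
  stopifnot(all(sigma2 >= 0))
  n_met <- length(sigma2)
  mets <- if (!is.null(names(sigma2))) names(sigma2) else sprintf("met%03d", seq_len(n_met))
  set.seed(seed)
  C <- ape::vcv(tree)
  U <- chol(C)  # C = t(U) %*% U
  n_sp <- nrow(C)
  vals <- matrix(0, n_sp, n_met, dimnames = list(rownames(C), mets))
  for (j in seq_len(n_met)) {
    if (sigma2[j] > 0) {
      vals[, j] <- as.numeric(t(U) %*% stats::rnorm(n_sp)) * sqrt(sigma2[j])
    }
  }
  if (!is.null(shift)) {
    stopifnot(all(shift$tips %in% rownames(vals)))
    vals[shift$tips, ] <- vals[shift$tips, ] + shift$magnitude
  }
  long <- expand.grid(replicate = seq_len(n_reps), species = rownames(vals),
                      metabolite = mets, stringsAsFactors = FALSE)
  base_val <- vals[cbind(long$species, long$metabolite)]
  noise <- if (replicate_noise_sd > 0) stats::rnorm(nrow(long), 0, replicate_noise_sd) else 0
  long$level <- 10^(base_val + noise)
  long$organ <- organ
  out <- trait_matrix(long[, c("organ", "species", "metabolite", "replicate", "level")])
  attr(out, "true_values") <- vals
  out
}

#' Toy kinetic model of a branched pathway with a cofactor cycle
#'
#' A fixed 8-reaction desk-scale network: a boundary source feeds A; A is
#' converted to B by a Michaelis-Menten step that consumes an ATP-like
#' cofactor; B continues to C (Michaelis-Menten) and branches to D (mass
#' action); C and D are exported by saturable sinks; a reversible
#' mass-action shunt links A and C; and the cofactor is regenerated from a
#' boundary precursor with product inhibition. The designated key fluxes are
#' the C export (\code{vC_out}) and the cofactor regeneration
#' (\code{vATP_regen}); both are nonzero at the wild-type steady state.
#'
#' @return A \code{kinetic_model} with 5 variable species (A, B, C, D, ATP)
#'   and 8 reactions; \code{attr(, "key_fluxes")} names the designated key
#'   set.
#' @export
toy_kinetic_model <- function() {
  m <- kinetic_model(
    name = "toy_branched_pathway",
    species = c(A = 1, B = 1, C = 1, D = 0.5, ATP = 1),
    boundary = c(X0 = 1, AXP = 1),
    reactions = list(
      v_in = list(stoich = c(X0 = -1, A = 1),
                  rate = "k_in * X0", params = c(k_in = 1)),
      vAB = list(stoich = c(A = -1, ATP = -1, B = 1),
                 rate = "Vm_ab * A / (Km_ab + A) * ATP / (Ka_ab + ATP)",
                 params = c(Vm_ab = 6, Km_ab = 1, Ka_ab = 0.5)),
      vBC = list(stoich = c(B = -1, C = 1),
                 rate = "Vm_bc * B / (Km_bc + B)",
                 params = c(Vm_bc = 2, Km_bc = 1)),
      vC_out = list(stoich = c(C = -1),
                    rate = "Vm_c * C / (Km_c + C)",
                    params = c(Vm_c = 2.5, Km_c = 1)),
      vBD = list(stoich = c(B = -1, D = 1),
                 rate = "k_bd * B", params = c(k_bd = 0.4)),
      vD_out = list(stoich = c(D = -1),
                    rate = "Vm_d * D / (Km_d + D)",
                    params = c(Vm_d = 2, Km_d = 1)),
      vAC_shunt = list(stoich = c(A = -1, C = 1),
                       rate = "k_f * A - k_r * C",
                       params = c(k_f = 0.3, k_r = 0.2)),
      vATP_regen = list(stoich = c(ATP = 1),
                        rate = "k_regen * AXP / (1 + ATP / Ki_regen)",
                        params = c(k_regen = 4, Ki_regen = 1))
    ))
  attr(m, "key_fluxes") <- c("vC_out", "vATP_regen")
  m
}

#' Planted feature table and disease labels for a conservation-score table
#'
#' Generates covariates with known ground truth against a fitted (or
#' simulated) conservation-score table: an abundance with a stated partial
#' R-squared to the log2 score, independent noise features, a random
#' chemical class, and a disease flag drawn with a stated odds ratio for
#' metabolites in the upper half of the score distribution.
#'
#' @param mcs Data.frame from [mcs_table()] (one or more organs).
#' @param partial_r2 Target fraction of residual (within-organ) score
#'   variance explained by the abundance feature (0 for an independent
#'   feature).
#' @param n_noise Number of independent standard-normal noise features.
#' @param disease_odds Odds ratio of the disease flag for above-median
#'   aggregate score (1 = no enrichment).
#' @param base_rate Disease probability for below-median metabolites.
#' @param seed RNG seed.
#' @return List: \code{features} (data.frame metabolite, abundance,
#'   noise1.., chem_class), \code{disease} (data.frame metabolite, flag,
#'   n_diseases), \code{provenance} (the generating parameters).
#' @export
synth_features_and_labels <- function(mcs, partial_r2 = 0.3, n_noise = 3,
                                      disease_odds = 6, base_rate = 0.2,
                                      seed = 1) {
  stopifnot(partial_r2 >= 0, partial_r2 < 1)
  set.seed(seed)
  ok <- mcs[!mcs$censored & is.finite(mcs$mcs), , drop = FALSE]
  y <- tapply(log2(ok$mcs), ok$metabolite, mean)  # per-metabolite mean log2 score
  mets <- names(y)
  n <- length(mets)
  ys <- as.numeric(scale(y))
  beta <- sqrt(partial_r2 / max(1 - partial_r2, 1e-12))
  abundance_log <- beta * ys + stats::rnorm(n)
  features <- data.frame(metabolite = mets,
                         abundance = 10^abundance_log,
                         stringsAsFactors = FALSE)
  for (k in seq_len(n_noise)) features[[paste0("noise", k)]] <- stats::rnorm(n)
  features$chem_class <- sample(c("amino_acid", "nucleotide", "sugar", "other"),
                                n, replace = TRUE)
  hi <- y > stats::median(y)
  odds0 <- base_rate / (1 - base_rate)
  p1 <- (odds0 * disease_odds) / (1 + odds0 * disease_odds)
  flag <- ifelse(hi, stats::rbinom(n, 1, p1), stats::rbinom(n, 1, base_rate)) == 1
  n_dis <- ifelse(flag, 1L + stats::rpois(n, ifelse(hi, 2, 0.5)), 0L)
  disease <- data.frame(metabolite = mets, flag = flag, n_diseases = n_dis,
                        stringsAsFactors = FALSE)
  list(features = features, disease = disease,
       provenance = list(partial_r2 = partial_r2, n_noise = n_noise,
                         disease_odds = disease_odds, base_rate = base_rate,
                         seed = seed))
}
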