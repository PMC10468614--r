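#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emulates the structure of a four-organ, multi-species metabolome survey:
# one time-calibrated phylogeny (depth 1), per-metabolite Brownian-motion
# rates spanning three decades (log-uniform on [1e-2, 1e1]), three replicate
# measurements with log10-scale noise SD 0.1, and organ-specific rate
# scalings so that organs differ in overall divergence. Feature and disease
# tables are planted downstream (stage 3/6) against the fitted scores.
#
#   Rscript analysis/01_simulate_data.R [--seed S] [--out results]

suppressPackageStartupMessages(library(metacons))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(f, d) { i <- which(args == f); if (length(i)) args[i + 1] else d }
seed <- as.integer(arg("--seed", "20260101"))
out <- arg("--out", "results")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_species <- 26            # species count of a typical mammalian panel
n_met <- 120               # metabolites scored per organ
organs <- c("brain", "heart", "kidney", "liver")
# brain/heart metabolomes diverge less overall than kidney/liver
organ_scale <- c(brain = 0.6, heart = 0.7, kidney = 1.0, liver = 1.2)

tree <- simulate_tree(n_species, birth_rate = 1, seed = seed)
ape::write.tree(tree, file.path(out, "tree.nwk"))

set.seed(seed + 1)
sigma2 <- 10^runif(n_met, -2, 1)
names(sigma2) <- sprintf("met%03d", seq_len(n_met))
write_tsv_provenance(
  data.frame(metabolite = names(sigma2), sigma2_true = sigma2),
  file.path(out, "true_rates.tsv"), seed = seed)

traits <- do.call(rbind, lapply(organs, function(org) {
  as.data.frame(simulate_bm_traits(
    tree, sigma2 * organ_scale[[org]], replicate_noise_sd = 0.1, n_reps = 3,
    seed = seed + match(org, organs), organ = org))
}))
write_tsv_provenance(traits, file.path(out, "traits.tsv"), seed = seed,
                     n_species = n_species, n_metabolites = n_met)

cat(sprintf("simulated %d species x %d metabolites x %d organs (%d rows) -> %s\n",
            n_species, n_met, length(organs), nrow(traits), out))
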