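Package: recoal
Title: Bayesian Inference of Ancestral Recombination Graphs from
    Recombining Nucleotide Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov chain Monte Carlo estimation of the posterior
    distribution of an ancestral recombination graph (ARG) and
    evolutionary-model parameters (scaled population size theta, scaled
    recombination rate rho, substitution-model parameters) conditional on
    an alignment of phased, recombining nucleotide sequences.  The data
    likelihood is the full Felsenstein likelihood of the ARG, computed by
    pruning over marginal-tree intervals with global column aliasing and
    partial recomputation restricted to the nodes and site ranges a
    proposal affects.  Includes a backward-time coalescent-with-
    recombination simulator that shares its event-rate convention with the
    prior density, sequence simulation along marginal trees under the F84
    and TN93 substitution models, reversible-jump proposal kernels over
    ARG space, Metropolis coupling across heated chains, and collectors
    for breakpoint space-time densities, per-site TMRCA profiles,
    consensus trees and effective sample sizes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    igraph,
    vcfR,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phangorn
Config/testthat/edition: 3
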