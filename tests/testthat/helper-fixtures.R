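# Small generating systems used across the suite.  All fixtures are built in
# code from seeded linear-Gaussian specs.

chain_spec <- function(n, b = 0.8, seed = 1) {
  simulation_spec(c("X", "Y", "Z"),
                  data.frame(from = c("X", "Y"), to = c("Y", "Z"), coef = c(b, b)),
                  n = n, seed = seed)
}

collider_spec <- function(n, b = 0.8, seed = 1) {
  simulation_spec(c("X", "Y", "Z"),
                  data.frame(from = c("X", "Y"), to = c("Z", "Z"), coef = c(b, b)),
                  n = n, seed = seed)
}

latent_pair_spec <- function(n, seed = 1, with_isolated = FALSE) {
  nodes <- data.frame(name = c("L", "X", "Y", if (with_isolated) "W"),
                      latent = c(TRUE, FALSE, FALSE, if (with_isolated) FALSE))
  simulation_spec(nodes,
                  data.frame(from = c("L", "L"), to = c("X", "Y"), coef = c(1, 1)),
                  n = n, seed = seed)
}

published_pag <- function() {
  # the generating DAG of the published model viewed as a fully directed PAG
  sim_spec_graph(build_published_model(n = 1))
}
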