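# Small, fast study configurations for unit tests (acceptance tests use the
# study-sized defaults).

tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 300,
    group_sizes = c(HD = 6, pSS = 5, SLE = 6),
    n_deg = 20, n_stim_genes = 20,
    ifn_set_size = 10,
    module_sizes = c(30, 20, 15),
    n_coexpr = 8,
    n_markers = 10,
    qc_dropout = 0,
    seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

tiny_sim <- function(seed = 1, ...) simulate_dataset(tiny_config(seed, ...))

# a deterministic toy ExpressionMatrix
toy_matrix <- function(values, layer = "fpkm",
                       genes = sprintf("g%02d", seq_len(nrow(values))),
                       samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, layer)
}
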