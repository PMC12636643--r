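# shared fixture builders (all data generated in code)

make_abund <- function(vals, scale = "raw",
                       proteins = sprintf("p%02d", seq_len(nrow(vals))),
                       samples = sprintf("s%02d", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(proteins, samples)
  abundance_matrix(vals, scale = scale)
}

small_cfg <- function(...) {
  sim_config(n_subjects = 60, n_proteins = 100, n_batches = 4,
             n_modules = 4, module_size = 10, ...)
}

# brute-force AUC over all positive-negative pairs, ties counted 1/2
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
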