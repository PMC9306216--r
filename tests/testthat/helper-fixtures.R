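# Shared fixture builders.

# two-group feature matrix (e.g. GH-family abundances) with one planted
# feature at a given fold change between groups
planted_features <- function(fold, n_per_group = 9, n_noise = 8,
                             base_rel = 5e-5, noise_sd = 0.2) {
  n <- 2 * n_per_group
  noise <- matrix(rlnorm(n_noise * n, log(1000), noise_sd), n_noise, n)
  planted <- rlnorm(n, log(1e7 * base_rel), noise_sd) *
    rep(c(1, fold), each = n_per_group)
  mat <- rbind(noise, planted = planted)
  rownames(mat) <- c(paste0("GH", seq_len(n_noise)), "planted")
  colnames(mat) <- paste0("s", seq_len(n))
  list(mat = mat,
       groups = setNames(rep(c("CON", "HG"), each = n_per_group),
                         colnames(mat)))
}
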