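# Shared fixture builders: everything is generated in code, nothing on disk.

# Minimal valid dataset: two values per generation.
toy_dataset <- function() {
  six_gen_dataset(list(
    generation_sample("P1", c(130.5, 128.0)),
    generation_sample("P2", c(70.25, 74.5)),
    generation_sample("F1", c(105.0, 111.75)),
    generation_sample("F2", c(88.0, 120.5)),
    generation_sample("BC1P1", c(125.0, 96.25)),
    generation_sample("BC1P2", c(81.5, 90.0))), cross_id = "toy")
}

toy_params <- function() {
  effect_params(m = 100, da = 10, db = -4, pd = 6, ph = 2, sigma2_e = 20,
                sigma2_pg = c(F2 = 5, BC1P1 = 12, BC1P2 = 3))
}

# Six-generation CSV text for read_dataset tests.
write_toy_csv <- function(path, drop_generation = NULL) {
  df <- as.data.frame(toy_dataset())
  if (!is.null(drop_generation)) df <- df[df$generation != drop_generation, ]
  utils::write.csv(df[c("generation", "value")], path, row.names = FALSE,
                   quote = FALSE)
  path
}

# Equal sample sizes for quick simulation-based tests.
flat_n <- function(n) {
  stats::setNames(rep(n, 6), c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2"))
}

# Independent brute-force enumeration of two-locus genotype classes used as
# the oracle for the registry structures: explicit loops, no shared code
# with build_structure().
brute_force_components <- function(generation, m, da, db, poly_shift) {
  locus <- switch(generation,
    F2    = list(u = c(1, 0, -1), f = c(1, 2, 1) / 4),
    BC1P1 = list(u = c(1, 0),     f = c(1, 1) / 2),
    BC1P2 = list(u = c(0, -1),    f = c(1, 1) / 2))
  w <- c(); mu <- c()
  for (a in seq_along(locus$u)) {
    for (b in seq_along(locus$u)) {
      w <- c(w, locus$f[a] * locus$f[b])
      mu <- c(mu, m + locus$u[a] * da + locus$u[b] * db + poly_shift)
    }
  }
  list(weights = w, means = mu)
}
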