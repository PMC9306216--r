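# Independent oracles and tiny fixture builders shared across tests.
# The oracles deliberately use brute-force loops/enumeration, not the
# package's vectorised code paths.

# a minimal hand-built knowledge base: two vitamins, explicit roles
tiny_kb <- function() {
  roles <- list(
    functional_role("THI.a", "THI", c("K00001", "K00002")),
    functional_role("THI.b", "THI", "K00003"),
    functional_role("THI.c", "THI", "K00004"),
    functional_role("RIB.a", "RIB", "K00010"),
    functional_role("RIB.b", "RIB", "K00011"))
  variants <- list(
    pathway_variant("THI.v1", "THI", c("THI.a", "THI.b"),
                    segment_tag = "branch_1"),
    pathway_variant("THI.v2", "THI", c("THI.a", "THI.c"),
                    segment_tag = "branch_2"),
    pathway_variant("RIB.v1", "RIB", c("RIB.a", "RIB.b")))
  knowledge_base(roles, variants, version = "tiny-test")
}

# brute-force capability checker: enumerates every variant and intersects
# role KO sets explicitly
oracle_producer <- function(ko_set, kb, vitamin) {
  verdict <- FALSE
  for (vr in kb$variants) {
    if (vr$vitamin != vitamin) next
    if (!is.null(vr$segment_tag) && vr$segment_tag == "post_cobyrinate") next
    ok <- TRUE
    for (rid in vr$indispensable_role_ids) {
      hit <- 0L
      for (ko in kb$roles[[rid]]$ko_ids) {
        if (ko %in% ko_set) hit <- hit + 1L
      }
      if (hit == 0L) { ok <- FALSE; break }
    }
    if (ok) verdict <- TRUE
  }
  verdict
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n+m, n) rank assignments (tie-free inputs only)
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  centre <- n * m / 2
  mean(abs(ws - centre) >= abs(w_obs - centre) - 1e-9)
}

# AMOVA Fs by direct loops over pairs (independent of the package's
# matrix-subset implementation)
oracle_amova_fs <- function(dm, labels) {
  n <- nrow(dm)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ss_total <- ss_total + dm[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) s <- s + dm[idx[a], idx[b]]^2
    }
    ss_within <- ss_within + s / length(idx)
  }
  k <- length(unique(labels))
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

# random small knowledge base + random genome KO subset, for agreement runs
random_kb_genome_pair <- function() {
  kb <- make_kb(seed = sample.int(1e6, 1),
                n_vitamins = sample(2:5, 1),
                roles_per_variant = sample(1:4, 1),
                variants_per_vitamin = sample(1:3, 1),
                kos_per_role = sample(1:3, 1))
  uni <- ko_universe(kb)
  ko_set <- uni[runif(length(uni)) < runif(1)]
  list(kb = kb, ko_set = ko_set)
}
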