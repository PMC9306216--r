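# TPM computation and KO/role/pathway/taxon aggregation.

two_gene_catalog <- function(lengths = c(1000, 1000)) {
  data.frame(gene_id = c("g1", "g2"), length_bp = lengths,
             ko_id = c("K00001", "K00002"),
             phylum = c("Bacteroidetes", ""),
             genus = c("Prevotella", ""),
             stringsAsFactors = FALSE)
}

test_that("TPM matches hand-computed two-gene fixtures", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(counts, two_gene_catalog())
  expect_equal(as.numeric(tpm), c(5e5, 5e5))

  # rates (9/3000, 1/1000) = (0.003, 0.001) -> 750000 / 250000
  counts2 <- matrix(c(9, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm2 <- compute_tpm(counts2, two_gene_catalog(c(3000, 1000)))
  expect_equal(as.numeric(tpm2), c(750000, 250000))
})

test_that("TPM columns sum to one million; zero columns stay zero", {
  withr::local_seed(3)
  for (rep in 1:20) {
    n <- sample(5:40, 1); m <- sample(2:6, 1)
    catalog <- data.frame(gene_id = paste0("g", 1:n),
                          length_bp = sample(300:3000, n, replace = TRUE),
                          ko_id = "", stringsAsFactors = FALSE)
    counts <- matrix(rpois(n * m, 40), n, m,
                     dimnames = list(catalog$gene_id, paste0("s", 1:m)))
    counts[, 1] <- 0L
    tpm <- compute_tpm(counts, catalog)
    expect_equal(unname(colSums(tpm)[-1]), rep(1e6, m - 1),
                 tolerance = 1e-6)
    expect_identical(unname(colSums(tpm)[1]), 0)
  }
})

test_that("TPM validates its inputs", {
  counts <- matrix(5, 1, 1, dimnames = list("missing", "s1"))
  expect_error(compute_tpm(counts, two_gene_catalog()), "absent from catalog")
  counts2 <- matrix(-1, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_error(compute_tpm(counts2, two_gene_catalog()), "negative")
  bad_cat <- two_gene_catalog(); bad_cat$length_bp[1] <- 0
  expect_error(compute_tpm(matrix(1, 2, 1,
                                  dimnames = list(c("g1", "g2"), "s1")),
                           bad_cat), "length")
})

test_that("TPM is scale invariant and length sensitive", {
  withr::local_seed(8)
  catalog <- data.frame(gene_id = paste0("g", 1:10),
                        length_bp = sample(300:3000, 10), ko_id = "",
                        stringsAsFactors = FALSE)
  counts <- matrix(rpois(20, 30) + 1L, 10, 2,
                   dimnames = list(catalog$gene_id, c("s1", "s2")))
  tpm <- compute_tpm(counts, catalog)
  scaled <- counts; scaled[, 1] <- scaled[, 1] * 7L
  expect_equal(compute_tpm(scaled, catalog)[, 1], tpm[, 1],
               tolerance = 1e-12)

  # doubling one gene's length decreases its TPM, increases all others
  catalog2 <- catalog; catalog2$length_bp[1] <- catalog$length_bp[1] * 2
  tpm2 <- compute_tpm(counts, catalog2)
  expect_true(all(tpm2[1, ] < tpm[1, ]))
  expect_true(all(tpm2[-1, ] > tpm[-1, ]))
})

test_that("KO aggregation is additive and skips unannotated genes", {
  catalog <- data.frame(gene_id = c("g1", "g2", "g3"),
                        length_bp = c(1000, 1000, 1000),
                        ko_id = c("K00001", "K00001", ""),
                        stringsAsFactors = FALSE)
  tpm <- matrix(c(100, 50, 10), 3, 1,
                dimnames = list(catalog$gene_id, "s1"))
  kop <- aggregate_ko(tpm, catalog)
  expect_equal(kop["K00001", "s1"], 150)
  expect_equal(nrow(kop), 1)  # unannotated gene contributes to no KO
})

test_that("role and pathway aggregation conserve abundance", {
  kb <- tiny_kb()
  samples <- c("s1", "s2")
  ko_profile <- matrix(c(10, 5, 2, 1, 7, 3, 20, 10, 4, 2, 14, 6),
                       nrow = 6,
                       dimnames = list(c("K00001", "K00002", "K00003",
                                         "K00004", "K00010", "K00011"),
                                       samples))
  roles <- aggregate_role(ko_profile, kb)
  expect_equal(roles["THI.a", "s1"], 15)  # K00001 + K00002
  expect_equal(roles["THI.b", "s1"], 2)
  pw <- pathway_abundance(ko_profile, kb)
  # each KO counted once even though THI.a is in both variants
  expect_equal(pw["THI", "s1"], 10 + 5 + 2 + 1)
  expect_equal(pw["RIB", "s1"], 10)
  # disjoint roles: role sums equal the pathway sum exactly
  expect_equal(sum(roles[c("THI.a", "THI.b", "THI.c"), "s2"]),
               pw["THI", "s2"], tolerance = 1e-9)
  # KOs absent from the profile contribute zero
  pw0 <- pathway_abundance(ko_profile[1:2, , drop = FALSE], kb)
  expect_equal(pw0["RIB", "s1"], 0)
})

test_that("taxon breakdown buckets unassigned genes and conserves totals", {
  kb <- tiny_kb()
  catalog <- data.frame(
    gene_id = paste0("g", 1:4), length_bp = rep(1000, 4),
    ko_id = c("K00001", "K00003", "K00010", "K00002"),
    phylum = c("Bacteroidetes", "Firmicutes", "Bacteroidetes", ""),
    genus = c("Prevotella", "Clostridium", "Bacteroides", ""),
    stringsAsFactors = FALSE)
  counts <- matrix(c(10, 20, 30, 40), 4, 1,
                   dimnames = list(catalog$gene_id, "s1"))
  tpm <- compute_tpm(counts, catalog)
  tb <- taxon_breakdown(tpm, catalog, kb, "THI", "phylum")
  expect_setequal(rownames(tb), c("Bacteroidetes", "Firmicutes",
                                  "unassigned"))
  kop <- aggregate_ko(tpm, catalog)
  pw <- pathway_abundance(kop, kb)
  expect_equal(sum(tb[, "s1"]), pw["THI", "s1"], tolerance = 1e-9)

  # single-phylum vitamin: 100% share
  tb_rib <- taxon_breakdown(tpm, catalog, kb, "RIB", "phylum")
  expect_identical(rownames(tb_rib), "Bacteroidetes")
  expect_equal(sum(tb_rib) / pw["RIB", "s1"], 1, ignore_attr = TRUE)

  expect_error(taxon_breakdown(tpm, catalog, kb, "XXX", "phylum"),
               "unknown vitamin")
})
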