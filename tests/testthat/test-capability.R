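# Genome capability classification, quality filtering, cobalamin typology.

test_that("quality filter applies strict bounds and preserves order", {
  gs <- list(
    genome_annotation("boundary", completeness = 90, contamination = 4),
    genome_annotation("good", completeness = 95, contamination = 4.9),
    genome_annotation("contaminated", completeness = 95, contamination = 5),
    genome_annotation("best", completeness = 99, contamination = 0.1))
  qf <- quality_filter(gs)
  expect_identical(vapply(qf$kept, `[[`, "", "genome_id"),
                   c("good", "best"))
  expect_identical(vapply(qf$rejected, `[[`, "", "genome_id"),
                   c("boundary", "contaminated"))

  bad <- list(genome_annotation("neg", completeness = 95,
                                contamination = -1))
  expect_error(quality_filter(bad), "neg")
})

test_that("corrected genome size rescales by completeness and contamination", {
  expect_equal(corrected_genome_size(
    genome_annotation("a", assembly_size = 2e6, completeness = 100,
                      contamination = 0)), 2e6)
  expect_equal(corrected_genome_size(
    genome_annotation("b", assembly_size = 1.8e6, completeness = 90,
                      contamination = 0)), 2e6)
  expect_equal(corrected_genome_size(
    genome_annotation("c", assembly_size = 2e6, completeness = 100,
                      contamination = 10)), 1.8e6)
  expect_error(corrected_genome_size(
    genome_annotation("d", completeness = 0)), "completeness 0")
})

test_that("capability calls: degenerate and saturated genomes", {
  kb <- tiny_kb()
  empty <- predict_capability(genome_annotation("e"), kb)
  expect_equal(empty$n_vitamins_producible, 0)
  expect_false(any(vapply(empty$vitamins, `[[`, NA, "producer")))

  full <- predict_capability(genome_annotation("f", ko_universe(kb)), kb)
  expect_equal(full$n_vitamins_producible, 2)
  # any single KO of a multi-KO role satisfies the role
  one_of_pair <- predict_capability(
    genome_annotation("g", c("K00002", "K00003")), kb)
  expect_true(one_of_pair$vitamins$THI$producer)
  expect_identical(one_of_pair$vitamins$THI$satisfied_variants, "THI.v1")
  expect_identical(
    one_of_pair$vitamins$THI$missing_indispensable$THI.v2, "THI.c")
})

test_that("capability is monotone under annotation growth", {
  withr::local_seed(42)
  for (rep in 1:20) {
    pair <- random_kb_genome_pair()
    uni <- ko_universe(pair$kb)
    extra <- setdiff(uni, pair$ko_set)
    superset <- c(pair$ko_set, extra[runif(length(extra)) < 0.5])
    base <- predict_capability(genome_annotation("a", pair$ko_set), pair$kb)
    grown <- predict_capability(genome_annotation("b", superset), pair$kb)
    for (vit in names(base$vitamins)) {
      if (base$vitamins[[vit]]$producer) {
        expect_true(grown$vitamins[[vit]]$producer)
      }
    }
  }
})

test_that("capability agrees with the brute-force variant checker", {
  withr::local_seed(7)
  for (rep in 1:100) {
    pair <- random_kb_genome_pair()
    call <- predict_capability(genome_annotation("g", pair$ko_set), pair$kb)
    for (vit in names(call$vitamins)) {
      expect_identical(call$vitamins[[vit]]$producer,
                       oracle_producer(pair$ko_set, pair$kb, vit),
                       info = paste("vitamin", vit, "rep", rep))
    }
  }
})

test_that("cobalamin archetypes reproduce the expected typology", {
  kb <- default_knowledge_base()
  anaer <- kb$variants[["COB.anaerobic_route"]]

  # complete anaerobic producer
  ccg_kos <- unlist(lapply(anaer$role_ids, function(r) kb$roles[[r]]$ko_ids))
  ccg <- classify_cobalamin(genome_annotation("ccg", ccg_kos), kb)
  expect_identical(ccg$biosynthesis_class, "complete")
  expect_true(predict_capability(genome_annotation("ccg", ccg_kos),
                                 kb)$vitamins$COB$producer)

  # Prevotella-like: anaerobic route minus cysG, cbiL, cbiJ, cbiT, cbiE
  lost <- paste0("COB.", c("cysG", "cbiL", "cbiJ", "cbiT", "cbiE"))
  prev_kos <- unlist(lapply(setdiff(anaer$role_ids, lost),
                            function(r) kb$roles[[r]]$ko_ids))
  prev_cap <- predict_capability(genome_annotation("prev", prev_kos), kb)
  expect_false(prev_cap$vitamins$COB$producer)
  expect_setequal(
    prev_cap$vitamins$COB$missing_indispensable$COB.anaerobic_route, lost)
  expect_identical(
    classify_cobalamin(genome_annotation("prev", prev_kos),
                       kb)$biosynthesis_class, "partial")

  # Methanobrevibacter-like: everything except MMAB and cobP
  cob_role_ids <- names(Filter(function(r) r$vitamin == "COB", kb$roles))
  mb_kos <- unlist(lapply(setdiff(cob_role_ids, c("COB.MMAB", "COB.cobP")),
                          function(r) kb$roles[[r]]$ko_ids))
  mb <- classify_cobalamin(genome_annotation("mb", mb_kos), kb)
  expect_identical(mb$biosynthesis_class, "partial")
  expect_setequal(mb$segments$post_cobyrinate$missing_indispensable_roles,
                  c("COB.MMAB", "COB.cobP"))

  # consumer-only genome: metH but no biosynthesis, no transporter
  meth <- classify_cobalamin(
    genome_annotation("metH_only",
                      kb$cobalamin_utilization$dependent_enzymes$metH), kb)
  expect_identical(meth$biosynthesis_class, "absent")
  expect_true(meth$has_dependent_enzyme)
  expect_false(meth$has_transporter)

  # nothing at all
  none <- classify_cobalamin(genome_annotation("none"), kb)
  expect_identical(none$biosynthesis_class, "absent")
  expect_false(none$has_transporter || none$has_dependent_enzyme)
})

test_that("cobalamin classes partition every genome", {
  kb <- make_kb(seed = 11, n_vitamins = 3, roles_per_variant = 2)
  withr::local_seed(5)
  uni <- ko_universe(kb)
  for (rep in 1:50) {
    kos <- uni[runif(length(uni)) < runif(1)]
    cl <- classify_cobalamin(genome_annotation("g", kos), kb)
    expect_true(cl$biosynthesis_class %in%
                  c("complete", "partial", "absent"))
    cob_present <- any(cl$role_presence)
    if (cl$biosynthesis_class == "absent") expect_false(cob_present)
    if (cl$biosynthesis_class == "partial") expect_true(cob_present)
  }
})

test_that("core KOs use a strict prevalence inequality", {
  gs <- c(
    lapply(1:9, function(i) genome_annotation(paste0("g", i),
                                              c("K00001", "K00002"))),
    list(genome_annotation("g10", "K00002")))
  core <- core_kos(gs, 0.9)
  expect_false("K00001" %in% core)  # 9/10 = 0.9, not > 0.9
  expect_true("K00002" %in% core)   # 10/10
  expect_error(core_kos(list(), 0.9), "empty")
})

test_that("exclusive core KOs honour both readings of 'only present'", {
  vpg <- lapply(1:10, function(i)
    genome_annotation(paste0("v", i), c("K00001", "K00002", "K00003")))
  # K00001 absent from NPGs; K00002 in one NPG; K00003 core in NPGs
  npg <- c(
    lapply(1:9, function(i) genome_annotation(paste0("n", i), "K00003")),
    list(genome_annotation("n10", c("K00002", "K00003"))))
  expect_identical(exclusive_core_kos(vpg, npg), "K00001")
  expect_setequal(exclusive_core_kos(vpg, npg, mode = "core_difference"),
                  c("K00001", "K00002"))
  expect_error(exclusive_core_kos(vpg, list()), "empty")
})

test_that("complementarity reports set cover and bottleneck roles", {
  kb <- default_knowledge_base()
  anaer <- kb$variants[["COB.anaerobic_route"]]
  half1 <- anaer$role_ids[1:8]
  half2 <- anaer$role_ids[-(1:8)]
  kos_of <- function(rids) unlist(lapply(rids, function(r)
    kb$roles[[r]]$ko_ids))
  cls <- list(
    classify_cobalamin(genome_annotation("a", kos_of(half1)), kb),
    classify_cobalamin(genome_annotation("b", kos_of(half2)), kb))
  comp <- complementarity_matrix(cls, kb)
  expect_true(comp$cover$covered)
  expect_identical(comp$cover$best_variant, "COB.anaerobic_route")
  expect_identical(dim(comp$matrix)[2], 2L)

  # both genomes missing cbiC -> negative cover with cbiC the bottleneck
  cls2 <- list(
    classify_cobalamin(
      genome_annotation("a", kos_of(setdiff(half1, "COB.cbiC"))), kb),
    classify_cobalamin(
      genome_annotation("b", kos_of(setdiff(half2, "COB.cbiC"))), kb))
  comp2 <- complementarity_matrix(cls2, kb)
  expect_false(comp2$cover$covered)
  expect_identical(comp2$cover$bottleneck_roles, "COB.cbiC")

  # a single complete genome covers alone
  ccg <- classify_cobalamin(
    genome_annotation("c", kos_of(anaer$role_ids)), kb)
  expect_true(complementarity_matrix(list(ccg), kb)$cover$covered)
})
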