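# Synthetic data with planted, machine-readable ground truth: knowledge
# bases, genomes with per-vitamin capabilities, and multi-group metagenome
# communities with planted pathway fold changes.

# small fixed taxonomy (5 phyla, 12 genera) echoing dominant rumen taxa so
# generated tables read naturally
taxa_ontology <- function() {
  list(
    Bacteroidetes = c("Prevotella", "Bacteroides", "Alistipes"),
    Firmicutes = c("Clostridium", "Ruminococcus", "Eubacterium", "Sharpea",
                   "Lachnospira"),
    Fibrobacteres = "Fibrobacter",
    Proteobacteria = c("Escherichia", "Succinivibrio"),
    Euryarchaeota = "Methanobrevibacter")
}

#' Generate a synthetic knowledge base
#'
#' A structurally valid knowledge base with configurable size: every
#' non-cobalamin vitamin gets \code{variants_per_vitamin} variants that share
#' a trunk of roles and differ in branch roles; cobalamin (always present)
#' gets the tri-segment structure — anaerobic and aerobic routes both ending
#' in a shared post-cobyrinate tail, plus the tail as a tagged segment
#' variant — and non-empty utilization lists. All roles are indispensable,
#' which keeps planted-truth arithmetic exact. KO ids are synthetic
#' (\code{K6####}, globally unique, so no vitamin shares KOs).
#'
#' @param seed Integer seed; the same seed yields a byte-identical base.
#' @param n_vitamins Number of vitamins, 1-9 (cobalamin always included).
#' @param roles_per_variant Roles per route (>= 1).
#' @param variants_per_vitamin Variants per non-cobalamin vitamin (>= 1).
#' @param kos_per_role KOs backing each role (>= 1).
#' @return A validated \code{vc_kb}.
#' @export
make_kb <- function(seed = 1, n_vitamins = 9, roles_per_variant = 3,
                    variants_per_vitamin = 2, kos_per_role = 2) {
  stopifnot(n_vitamins >= 1, n_vitamins <= 9, roles_per_variant >= 1,
            variants_per_vitamin >= 1, kos_per_role >= 1)
  vits <- unique(c("COB", vitamin_codes()))[seq_len(n_vitamins)]

  withr::with_seed(seed, {
    ko_pool <- sample(sprintf("K6%04d", seq_len(9999)))
    ko_cursor <- 0L
    next_kos <- function(k) {
      ids <- ko_pool[ko_cursor + seq_len(k)]
      ko_cursor <<- ko_cursor + k
      ids
    }
    roles <- list(); variants <- list()
    add_role <- function(vit, idx) {
      rid <- sprintf("%s.r%02d", vit, idx)
      roles[[rid]] <<- functional_role(rid, vit, next_kos(kos_per_role))
      rid
    }
    for (vit in vits) {
      if (vit == "COB") {
        anaer <- vapply(seq_len(roles_per_variant), function(i)
          add_role(vit, i), "")
        aer <- vapply(roles_per_variant + seq_len(roles_per_variant),
                      function(i) add_role(vit, i), "")
        n_post <- max(1L, roles_per_variant - 1L)
        post <- vapply(2L * roles_per_variant + seq_len(n_post),
                       function(i) add_role(vit, i), "")
        variants[["COB.anaerobic_route"]] <- pathway_variant(
          "COB.anaerobic_route", vit, c(anaer, post),
          segment_tag = "anaerobic")
        variants[["COB.aerobic_route"]] <- pathway_variant(
          "COB.aerobic_route", vit, c(aer, post), segment_tag = "aerobic")
        variants[["COB.post_cobyrinate"]] <- pathway_variant(
          "COB.post_cobyrinate", vit, post, segment_tag = "post_cobyrinate")
      } else {
        n_trunk <- roles_per_variant %/% 2L
        trunk <- if (n_trunk > 0)
          vapply(seq_len(n_trunk), function(i) add_role(vit, i), "")
          else character()
        idx <- n_trunk
        for (b in seq_len(variants_per_vitamin)) {
          n_branch <- roles_per_variant - n_trunk
          branch <- if (n_branch > 0)
            vapply(idx + seq_len(n_branch), function(i) add_role(vit, i), "")
            else character()
          idx <- idx + length(branch)
          vid <- sprintf("%s.v%d", vit, b)
          variants[[vid]] <- pathway_variant(
            vid, vit, c(trunk, branch),
            segment_tag = if (variants_per_vitamin > 1)
              sprintf("branch_%d", b) else NULL)
        }
      }
    }
    util <- list(
      transporters = list(btuB = next_kos(1), btuF = next_kos(1),
                          cbrT = next_kos(1)),
      dependent_enzymes = list(metH = next_kos(1), MCM = next_kos(1),
                               nrdJ = next_kos(1)))
    kb <- knowledge_base(roles, variants, util,
                         version = sprintf("synthetic-seed%d", seed))
    viol <- validate_knowledge_base(kb)
    if (length(viol)) {
      stop("internal error: generated knowledge base invalid:\n",
           paste(viol, collapse = "\n"))
    }
    kb
  })
}

#' Retention probability of a variant under annotation dropout
#'
#' If every KO is independently dropped with probability \code{dropout}, a
#' planted producer still satisfies a variant with probability
#' \eqn{\prod_r (1 - d^{k_r})} over the variant's indispensable roles, where
#' \eqn{k_r} is the role's KO count.
#'
#' @param variant A \code{vc_variant}.
#' @param kb The knowledge base it lives in.
#' @param dropout Dropout probability in [0, 1).
#' @return Probability in (0, 1].
#' @export
variant_retention_probability <- function(variant, kb, dropout) {
  prod(vapply(variant$indispensable_role_ids, function(rid)
    1 - dropout^length(kb$roles[[rid]]$ko_ids), 0))
}

#' Simulate genomes with planted per-vitamin capabilities
#'
#' Planted producers of a vitamin receive every KO of every indispensable
#' role of one randomly chosen de novo route (plus non-indispensable roles
#' at 50\% each); non-producers receive a random subset of the vitamin's KOs
#' from which one indispensable role per route has been fully removed, so no
#' route can be satisfied and the planted truth is unambiguous. Annotation
#' dropout is applied afterwards, KO-wise; the truth records the pre-dropout
#' intent. Genome quality numbers are drawn in the high-quality range and
#' taxonomy from a small fixed ontology.
#'
#' @param kb A validated knowledge base.
#' @param n_genomes Number of genomes.
#' @param capability_design Named per-vitamin producer fractions in [0, 1]
#'   (unnamed scalar recycles to all vitamins; default 0.3).
#' @param dropout KO dropout probability in [0, 1).
#' @param seed Integer seed.
#' @return List with \code{genomes} (list of \code{vc_genome}) and
#'   \code{truth}: \code{capabilities} (genome x vitamin logical
#'   data.frame), \code{chosen_variant}, \code{cobalamin_class} (planted,
#'   pre-dropout), \code{seed}, \code{params}.
#' @export
simulate_genomes <- function(kb, n_genomes, capability_design = 0.3,
                             dropout = 0, seed = 1) {
  vits <- kb_vitamins(kb)
  if (is.null(names(capability_design))) {
    capability_design <- setNames(rep(capability_design[1], length(vits)),
                                  vits)
  }
  capability_design[setdiff(vits, names(capability_design))] <- 0
  if (any(capability_design < 0 | capability_design > 1)) {
    stop("producer fractions must lie in [0, 1]", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must lie in [0, 1)", call. = FALSE)
  }
  ont <- taxa_ontology()
  genera <- unlist(ont, use.names = FALSE)
  phylum_of <- rep(names(ont), lengths(ont))

  withr::with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(n_genomes))
    cap <- matrix(FALSE, n_genomes, length(vits),
                  dimnames = list(ids, vits))
    chosen <- matrix(NA_character_, n_genomes, length(vits),
                     dimnames = list(ids, vits))
    genomes <- vector("list", n_genomes)
    planted_sets <- vector("list", n_genomes)
    for (i in seq_len(n_genomes)) {
      kos <- character()
      for (vit in vits) {
        routes <- kb_route_variants(kb, vit)
        if (runif(1) < capability_design[[vit]]) {
          cap[i, vit] <- TRUE
          vr <- routes[[sample.int(length(routes), 1)]]
          chosen[i, vit] <- vr$variant_id
          kos <- c(kos, unlist(lapply(vr$indispensable_role_ids, function(rid)
            kb$roles[[rid]]$ko_ids)))
          extra <- setdiff(vr$role_ids, vr$indispensable_role_ids)
          for (rid in extra) {
            if (runif(1) < 0.5) kos <- c(kos, kb$roles[[rid]]$ko_ids)
          }
        } else {
          knockout <- unique(vapply(routes, function(vr)
            vr$indispensable_role_ids[
              sample.int(length(vr$indispensable_role_ids), 1)], ""))
          blocked <- unlist(lapply(knockout, function(rid)
            kb$roles[[rid]]$ko_ids))
          pool <- setdiff(ko_universe(kb, vit), blocked)
          take <- pool[runif(length(pool)) < 0.5]
          kos <- c(kos, take)
        }
      }
      gi <- sample.int(length(genera), 1)
      planted_sets[[i]] <- unique(kos)
      genomes[[i]] <- genome_annotation(
        ids[i], ko_set = unique(kos),
        completeness = runif(1, 92, 99.9),
        contamination = runif(1, 0, 4.9),
        taxonomy = c(domain = if (phylum_of[gi] == "Euryarchaeota")
                       "Archaea" else "Bacteria",
                     phylum = phylum_of[gi], genus = genera[gi]),
        assembly_size = round(runif(1, 1.5e6, 4.5e6)))
    }
    cob_class <- if ("COB" %in% vits) {
      vapply(genomes, function(g)
        classify_cobalamin(g, kb)$biosynthesis_class, "")
    } else rep(NA_character_, n_genomes)
    names(cob_class) <- ids
    if (dropout > 0) {
      for (i in seq_len(n_genomes)) {
        keep <- runif(length(genomes[[i]]$ko_set)) >= dropout
        genomes[[i]]$ko_set <- genomes[[i]]$ko_set[keep]
      }
    }
    list(genomes = genomes,
         truth = list(
           capabilities = as.data.frame(cap),
           chosen_variant = as.data.frame(chosen),
           cobalamin_class = cob_class,
           seed = seed,
           params = list(n_genomes = n_genomes,
                         capability_design = as.list(capability_design),
                         dropout = dropout)))
  })
}

#' Simulate a multi-group metagenome community
#'
#' Builds a gene catalog from the genomes' KO contents (one gene per genome
#' x KO, lengths uniform on 300-3000 bp, taxonomy inherited from the
#' genome) plus unannotated background genes at roughly prokaryotic gene
#' density (one gene per \code{bp_per_background_gene} of assembly), so
#' vitamin genes are a small fraction of the catalog, as in a real
#' whole-metagenome gene catalog, and the TPM denominator is dominated by
#' the background. Each genome gets a lognormal baseline abundance;
#' per-vitamin fold changes are applied to the later groups' vitamin genes
#' so the planted pathway fold changes hold in expectation; per-genome
#' abundance is jittered per sample (lognormal, sd \code{noise_sd}) and
#' read counts are sampled multinomially at fixed depth. Deterministic per
#' seed.
#'
#' @param kb A validated knowledge base.
#' @param genomes List of \code{vc_genome} (e.g. from
#'   \code{\link{simulate_genomes}}).
#' @param n_groups Number of sample groups (>= 2).
#' @param samples_per_group Samples per group.
#' @param fold_changes Named per-vitamin fold change vector applied to every
#'   group after the first (two-group shorthand), or a vitamin x group
#'   matrix whose first column is ignored (baseline 1). Values must be > 0;
#'   unnamed vitamins default to 1.
#' @param sequencing_depth Reads per sample (>= 1000).
#' @param noise_sd Lognormal sd of the per-sample per-genome abundance
#'   jitter (default 0.3).
#' @param bp_per_background_gene Assembly base pairs per unannotated
#'   background gene (default 2000; set \code{Inf} for a vitamin-genes-only
#'   catalog).
#' @param group_labels Optional group names (default CON/HG for two groups).
#' @param seed Integer seed.
#' @return List of class \code{vc_dataset}: \code{kb}, \code{genomes},
#'   \code{catalog} (data.frame), \code{counts} (gene x sample integer
#'   matrix), \code{sample_metadata} (data.frame sample_id, group),
#'   \code{truth} (group labels, fold design, analytic expected pathway TPM
#'   per group, planted phylum shares, seed, params).
#' @export
simulate_community <- function(kb, genomes, n_groups = 2,
                               samples_per_group = 12, fold_changes = NULL,
                               sequencing_depth = 1e6, noise_sd = 0.3,
                               bp_per_background_gene = 2000,
                               group_labels = NULL, seed = 1) {
  stopifnot(n_groups >= 2, samples_per_group >= 1)
  if (sequencing_depth < 1000) {
    stop("sequencing_depth must be at least 1000 reads/sample",
         call. = FALSE)
  }
  vits <- kb_vitamins(kb)
  fold <- matrix(1, length(vits), n_groups, dimnames = list(vits, NULL))
  if (!is.null(fold_changes)) {
    if (is.matrix(fold_changes)) {
      fold[rownames(fold_changes), ] <- fold_changes
      fold[, 1] <- 1
    } else {
      for (vit in names(fold_changes)) {
        fold[vit, -1] <- fold_changes[[vit]]
      }
    }
  }
  if (any(fold <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 2) c("CON", "HG")
                    else sprintf("G%d", seq_len(n_groups))
  }
  stopifnot(length(group_labels) == n_groups)
  colnames(fold) <- group_labels

  withr::with_seed(seed, {
    # gene catalog: one gene per genome x KO
    recs <- lapply(genomes, function(g) {
      n_bg <- if (is.finite(bp_per_background_gene))
        max(0L, round(g$assembly_size / bp_per_background_gene)) else 0L
      ids <- c(g$ko_set, if (n_bg > 0) sprintf("bg%05d", seq_len(n_bg)))
      if (length(ids) == 0L) return(NULL)
      data.frame(gene_id = paste0(g$genome_id, "_", ids),
                 length_bp = round(runif(length(ids), 300, 3000)),
                 ko_id = c(g$ko_set, character(n_bg)),
                 phylum = unname(g$taxonomy["phylum"]),
                 genus = unname(g$taxonomy["genus"]),
                 genome_id = g$genome_id,
                 stringsAsFactors = FALSE)
    })
    catalog <- do.call(rbind, recs)
    if (is.null(catalog) || nrow(catalog) == 0L) {
      stop("genomes carry no KOs; nothing to simulate", call. = FALSE)
    }
    genome_ids <- vapply(genomes, `[[`, "", "genome_id")
    base_abund <- setNames(rlnorm(length(genomes), 0, 1), genome_ids)

    # map each gene to its vitamin (synthetic KOs are vitamin-unique; with a
    # shared-KO base the first owning vitamin wins)
    ko2vit <- setNames(rep(NA_character_, 0), character())
    for (vit in vits) {
      kos <- ko_universe(kb, vit)
      new <- setdiff(kos, names(ko2vit))
      ko2vit[new] <- vit
    }
    gene_vit <- ko2vit[catalog$ko_id]

    gene_abund <- base_abund[catalog$genome_id]
    base_weight <- gene_abund * catalog$length_bp  # expected reads at fold 1

    n_samples <- n_groups * samples_per_group
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    sample_group <- rep(group_labels, each = samples_per_group)
    counts <- matrix(0L, nrow(catalog), n_samples,
                     dimnames = list(catalog$gene_id, sample_ids))
    for (s in seq_len(n_samples)) {
      gf <- rep(1, nrow(catalog))
      hit <- !is.na(gene_vit)
      gf[hit] <- fold[cbind(gene_vit[hit],
                            rep(sample_group[s], sum(hit)))]
      jitter <- rlnorm(length(genomes), 0, noise_sd)
      names(jitter) <- genome_ids
      w <- base_weight * gf * jitter[catalog$genome_id]
      counts[, s] <- rmultinom(1, sequencing_depth, w / sum(w))[, 1]
    }

    # analytic expected pathway TPM per group (ratio of expectations)
    rate <- gene_abund  # expected reads / length
    expected_tpm <- vapply(seq_len(n_groups), function(gidx) {
      gf <- rep(1, nrow(catalog))
      hit <- !is.na(gene_vit)
      gf[hit] <- fold[cbind(gene_vit[hit],
                            rep(group_labels[gidx], sum(hit)))]
      r <- rate * gf
      vapply(vits, function(vit)
        1e6 * sum(r[!is.na(gene_vit) & gene_vit == vit]) / sum(r), 0)
    }, numeric(length(vits)))
    dimnames(expected_tpm) <- list(vits, group_labels)

    phylum_shares <- tapply(base_weight / catalog$length_bp, catalog$phylum,
                            sum)
    phylum_shares <- phylum_shares / sum(phylum_shares)

    structure(
      list(kb = kb, genomes = genomes, catalog = catalog, counts = counts,
           sample_metadata = data.frame(sample_id = sample_ids,
                                        group = sample_group,
                                        stringsAsFactors = FALSE),
           truth = list(group_of_sample = setNames(sample_group, sample_ids),
                        fold_design = fold,
                        expected_pathway_tpm = expected_tpm,
                        phylum_shares = as.list(phylum_shares),
                        seed = seed,
                        params = list(
                          n_groups = n_groups,
                          samples_per_group = samples_per_group,
                          sequencing_depth = sequencing_depth,
                          noise_sd = noise_sd,
                          bp_per_background_gene = bp_per_background_gene))),
      class = "vc_dataset")
  })
}

#' Preset synthetic study designs
#'
#' Self-contained datasets mirroring the package's two study designs.
#' \code{"diet"}: two groups (CON vs HG), 12 samples each at depth 1e6,
#' planted fold changes — cobalamin 0.5 (inhibited), pyridoxine 1.0
#' (unchanged), all other vitamins 1.3 (enhanced). \code{"region"}: three
#' gut regions (RUM/ILE/CEC), 8 samples each, with thiamine, niacin and
#' pyridoxine enriched 1.5-fold in the large-intestine group (CEC).
#'
#' @param preset \code{"diet"} or \code{"region"}.
#' @param seed Integer seed driving knowledge base, genomes and community.
#' @param n_genomes Number of genomes underlying the community (default 80).
#' @param sequencing_depth Reads per sample (default 1e6).
#' @return A \code{vc_dataset} (see \code{\link{simulate_community}}).
#' @export
simulate_preset <- function(preset = c("diet", "region"), seed = 1,
                            n_genomes = 80, sequencing_depth = 1e6) {
  preset <- match.arg(preset)
  kb <- make_kb(seed, n_vitamins = 9, roles_per_variant = 3,
                variants_per_vitamin = 2, kos_per_role = 2)
  sg <- simulate_genomes(kb, n_genomes, capability_design = 0.3,
                         dropout = 0, seed = seed + 1)
  if (preset == "diet") {
    folds <- setNames(rep(1.3, 9), kb_vitamins(kb))
    folds["COB"] <- 0.5
    folds["PYR"] <- 1.0
    simulate_community(kb, sg$genomes, n_groups = 2, samples_per_group = 12,
                       fold_changes = folds,
                       sequencing_depth = sequencing_depth,
                       seed = seed + 2)
  } else {
    vits <- kb_vitamins(kb)
    fold <- matrix(1, length(vits), 3,
                   dimnames = list(vits, c("RUM", "ILE", "CEC")))
    fold[c("THI", "NIA", "PYR"), "CEC"] <- 1.5
    simulate_community(kb, sg$genomes, n_groups = 3, samples_per_group = 8,
                       fold_changes = fold,
                       sequencing_depth = sequencing_depth,
                       group_labels = c("RUM", "ILE", "CEC"),
                       seed = seed + 2)
  }
}
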