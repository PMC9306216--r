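# Genome-level capability classification: which vitamins can a genome make
# de novo, and where does it sit in the cobalamin producer/consumer typology.

#' Construct a genome annotation
#'
#' Holds a genome's KO content together with the CheckM-style quality numbers
#' and taxonomy consumed from upstream tools.
#'
#' @param genome_id Unique genome identifier.
#' @param ko_set Character vector of KO ids annotated on the genome (may be
#'   empty; KOs outside the knowledge base are allowed and ignored during
#'   classification).
#' @param completeness Estimated completeness, percent in [0, 100].
#' @param contamination Estimated contamination, percent >= 0.
#' @param taxonomy Named character vector, any of
#'   \code{c("domain","phylum","class","order","family","genus")}; missing
#'   ranks may be absent or empty strings.
#' @param assembly_size Assembly length in base pairs (> 0).
#' @param source_region Optional label (e.g. a GIT region).
#' @return A list of class \code{vc_genome}.
#' @export
genome_annotation <- function(genome_id, ko_set = character(),
                              completeness = 100, contamination = 0,
                              taxonomy = character(), assembly_size = 2e6,
                              source_region = NULL) {
  structure(
    list(genome_id = as.character(genome_id),
         ko_set = unique(as.character(ko_set)),
         completeness = as.numeric(completeness),
         contamination = as.numeric(contamination),
         taxonomy = taxonomy,
         assembly_size = as.numeric(assembly_size),
         source_region = source_region),
    class = "vc_genome")
}

#' Filter genomes on completeness and contamination
#'
#' Keeps genomes with completeness strictly greater than
#' \code{min_completeness} and contamination strictly less than
#' \code{max_contamination} (the conventional "high quality" gate for
#' metagenome-assembled genomes; boundary genomes are rejected). Input order
#' is preserved in both partitions.
#'
#' @param genomes List of \code{\link{genome_annotation}} objects.
#' @param min_completeness Threshold percent (default 90).
#' @param max_contamination Threshold percent (default 5).
#' @return List with elements \code{kept} and \code{rejected}.
#' @export
quality_filter <- function(genomes, min_completeness = 90,
                           max_contamination = 5) {
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_contamination >= 0, max_contamination <= 100)
  for (g in genomes) {
    if (is.na(g$completeness) || is.na(g$contamination) ||
        g$contamination < 0 || g$completeness > 100 || g$completeness < 0) {
      stop("malformed quality record for genome ", g$genome_id,
           " (completeness=", g$completeness,
           ", contamination=", g$contamination, ")", call. = FALSE)
    }
  }
  keep <- vapply(genomes, function(g) {
    g$completeness > min_completeness && g$contamination < max_contamination
  }, NA)
  list(kept = genomes[keep], rejected = genomes[!keep])
}

#' Completeness/contamination-corrected genome size
#'
#' Rescales the assembly length to an estimate of the true genome size:
#' \code{assembly_size * (100 / completeness) * (1 - contamination / 100)}.
#'
#' @param g A \code{\link{genome_annotation}}.
#' @return Corrected size in base pairs.
#' @export
corrected_genome_size <- function(g) {
  if (g$completeness <= 0) {
    stop("cannot correct genome size with completeness 0 (genome ",
         g$genome_id, ")", call. = FALSE)
  }
  g$assembly_size * (100 / g$completeness) * (1 - g$contamination / 100)
}

# does the genome's KO set satisfy a variant? (every indispensable role has
# at least one of its KOs present)
variant_satisfied <- function(ko_set, variant, kb) {
  all(vapply(variant$indispensable_role_ids, function(rid) {
    any(kb$roles[[rid]]$ko_ids %in% ko_set)
  }, NA))
}

#' Predict per-vitamin de novo biosynthesis capability
#'
#' A genome is called a producer of a vitamin if, for at least one de novo
#' pathway variant, every indispensable functional role is represented by at
#' least one of its KOs in the genome.  Cobalamin segment-only variants
#' (tagged \code{post_cobyrinate}) are the shared pathway tail and do not
#' count as stand-alone routes.  Unknown KOs in the annotation are ignored.
#' The call is deterministic and monotone: adding KOs can only add producer
#' verdicts.
#'
#' @param g A \code{\link{genome_annotation}}.
#' @param kb A validated knowledge base.
#' @return A list of class \code{vc_capability}: \code{genome_id},
#'   \code{vitamins} (named list per vitamin with \code{producer},
#'   \code{satisfied_variants} and per-variant \code{missing_indispensable}),
#'   and \code{n_vitamins_producible}.
#' @export
predict_capability <- function(g, kb) {
  vits <- kb_vitamins(kb)
  per_vit <- lapply(vits, function(vit) {
    routes <- kb_route_variants(kb, vit)
    missing <- lapply(routes, function(vr) {
      vr$indispensable_role_ids[!vapply(vr$indispensable_role_ids,
        function(rid) any(kb$roles[[rid]]$ko_ids %in% g$ko_set), NA)]
    })
    names(missing) <- vapply(routes, `[[`, "", "variant_id")
    sat <- names(missing)[vapply(missing, length, 0L) == 0L]
    list(producer = length(sat) > 0L, satisfied_variants = sat,
         missing_indispensable = missing)
  })
  names(per_vit) <- vits
  structure(
    list(genome_id = g$genome_id, vitamins = per_vit,
         n_vitamins_producible = sum(vapply(per_vit, `[[`, NA, "producer"))),
    class = "vc_capability")
}

#' Capability table for a set of genomes
#'
#' @param genomes List of \code{\link{genome_annotation}} objects.
#' @param kb A validated knowledge base.
#' @return data.frame with one row per genome: \code{genome_id}, one 0/1
#'   column per vitamin, \code{n_vitamins}, and a comma-separated
#'   \code{satisfied_variants} column.
#' @export
predict_capability_all <- function(genomes, kb) {
  calls <- lapply(genomes, predict_capability, kb = kb)
  vits <- kb_vitamins(kb)
  out <- data.frame(genome_id = vapply(calls, `[[`, "", "genome_id"),
                    stringsAsFactors = FALSE)
  for (vit in vits) {
    out[[vit]] <- vapply(calls, function(cl)
      as.integer(cl$vitamins[[vit]]$producer), 0L)
  }
  out$n_vitamins <- vapply(calls, `[[`, 0L, "n_vitamins_producible")
  out$satisfied_variants <- vapply(calls, function(cl) {
    paste(unlist(lapply(cl$vitamins, `[[`, "satisfied_variants")),
          collapse = ",")
  }, "")
  out
}

#' Classify a genome in the cobalamin producer/consumer typology
#'
#' Three independent facets: (i) biosynthesis class — \code{"complete"} if
#' some (anaerobic or aerobic) route including the post-cobyrinate tail is
#' fully satisfied, \code{"partial"} if at least one cobalamin biosynthesis
#' role is present but no route is complete, \code{"absent"} otherwise;
#' (ii) presence of any cobalamin transporter gene (btuB/btuF/btuC/btuD/
#' cbrT/cbrV); (iii) presence of any cobalamin-dependent enzyme (metH, MCM,
#' nrdJ, ...). Transporter presence requires any single gene, not a complete
#' ABC system.
#'
#' @param g A \code{\link{genome_annotation}}.
#' @param kb A validated knowledge base containing cobalamin.
#' @return A list of class \code{vc_cobalamin}: \code{genome_id},
#'   \code{biosynthesis_class}, \code{has_transporter},
#'   \code{has_dependent_enzyme}, per-segment \code{segments} (present and
#'   missing indispensable roles for anaerobic/aerobic/post_cobyrinate),
#'   and named logical vectors \code{role_presence},
#'   \code{transporter_presence}, \code{enzyme_presence}.
#' @export
classify_cobalamin <- function(g, kb) {
  if (!"COB" %in% kb_vitamins(kb)) {
    stop("knowledge base has no cobalamin (COB) pathway", call. = FALSE)
  }
  cob_roles <- Filter(function(r) identical(r$vitamin, "COB"), kb$roles)
  role_presence <- vapply(cob_roles, function(r) any(r$ko_ids %in% g$ko_set),
                          NA)
  names(role_presence) <- vapply(cob_roles, `[[`, "", "role_id")
  routes <- kb_route_variants(kb, "COB")
  complete <- any(vapply(routes, variant_satisfied, NA,
                         ko_set = g$ko_set, kb = kb))
  cls <- if (complete) "complete"
         else if (any(role_presence)) "partial"
         else "absent"

  segs <- cob_segment_roles(kb)
  seg_report <- lapply(segs, function(rids) {
    pres <- rids[rids %in% names(role_presence)[role_presence]]
    list(present_roles = pres, missing_indispensable_roles = setdiff(rids, pres))
  })

  util <- kb$cobalamin_utilization
  tr_pres <- vapply(util$transporters, function(kos) any(kos %in% g$ko_set), NA)
  en_pres <- vapply(util$dependent_enzymes, function(kos) any(kos %in% g$ko_set), NA)
  structure(
    list(genome_id = g$genome_id, biosynthesis_class = cls,
         has_transporter = any(tr_pres), has_dependent_enzyme = any(en_pres),
         segments = seg_report, role_presence = role_presence,
         transporter_presence = tr_pres, enzyme_presence = en_pres),
    class = "vc_cobalamin")
}

#' Cobalamin class table for a set of genomes
#'
#' @param genomes List of \code{\link{genome_annotation}} objects.
#' @param kb A validated knowledge base containing cobalamin.
#' @return data.frame with \code{genome_id}, \code{biosynthesis_class},
#'   \code{has_transporter}, \code{has_dependent_enzyme}.
#' @export
classify_cobalamin_all <- function(genomes, kb) {
  cls <- lapply(genomes, classify_cobalamin, kb = kb)
  data.frame(
    genome_id = vapply(cls, `[[`, "", "genome_id"),
    biosynthesis_class = vapply(cls, `[[`, "", "biosynthesis_class"),
    has_transporter = vapply(cls, `[[`, NA, "has_transporter"),
    has_dependent_enzyme = vapply(cls, `[[`, NA, "has_dependent_enzyme"),
    stringsAsFactors = FALSE)
}

#' Core KOs of a genome group
#'
#' KOs present in strictly more than \code{prevalence_threshold} of the
#' group's genomes ("more than 90\%" is a strict inequality: a KO in exactly
#' 9 of 10 genomes is not core at threshold 0.9).
#'
#' @param group Non-empty list of \code{\link{genome_annotation}} objects.
#' @param prevalence_threshold Fraction in (0, 1); default 0.9.
#' @return Character vector of core KO ids.
#' @export
core_kos <- function(group, prevalence_threshold = 0.9) {
  if (length(group) == 0L) stop("empty genome group", call. = FALSE)
  stopifnot(prevalence_threshold > 0, prevalence_threshold < 1)
  tab <- table(unlist(lapply(group, `[[`, "ko_set")))
  names(tab)[tab / length(group) > prevalence_threshold]
}

#' Core KOs exclusive to the producer group
#'
#' Core KOs of the vitamin-producing genomes (VPGs) that are absent from the
#' non-producing genomes (NPGs). Two readings of "only present in VPGs" are
#' offered: the default \code{"strict"} removes any KO occurring in even a
#' single NPG genome (existence reading); \code{"core_difference"} removes
#' only KOs that are also core in NPGs.
#'
#' @param vpg_group,npg_group Non-empty genome lists.
#' @param prevalence_threshold Fraction in (0, 1); default 0.9.
#' @param mode \code{"strict"} (default) or \code{"core_difference"}.
#' @return Character vector of KO ids.
#' @export
exclusive_core_kos <- function(vpg_group, npg_group,
                               prevalence_threshold = 0.9,
                               mode = c("strict", "core_difference")) {
  if (length(vpg_group) == 0L || length(npg_group) == 0L) {
    stop("empty genome group", call. = FALSE)
  }
  mode <- match.arg(mode)
  core_v <- core_kos(vpg_group, prevalence_threshold)
  if (mode == "strict") {
    setdiff(core_v, unique(unlist(lapply(npg_group, `[[`, "ko_set"))))
  } else {
    setdiff(core_v, core_kos(npg_group, prevalence_threshold))
  }
}

#' Cobalamin role complementarity across genomes
#'
#' Binary presence table of all cobalamin roles (biosynthesis segments in
#' pathway order, then transporters, then dependent enzymes) across genomes,
#' plus a set-cover report: does the union of the genomes' roles satisfy a
#' complete de novo route?  Useful to ask whether partial producers could
#' synthesize cobalamin collaboratively.
#'
#' @param classes Non-empty list of \code{\link{classify_cobalamin}} results.
#' @param kb The knowledge base the classes were derived from.
#' @return List with \code{matrix} (roles x genomes, 0/1) and \code{cover}
#'   (list: \code{covered} flag, \code{best_variant},
#'   \code{bottleneck_roles} — indispensable roles missing from the union
#'   under the best route).
#' @export
complementarity_matrix <- function(classes, kb) {
  if (length(classes) == 0L) stop("no genomes supplied", call. = FALSE)
  segs <- cob_segment_roles(kb)
  bio_order <- unique(c(segs$anaerobic, segs$aerobic, segs$post_cobyrinate))
  rows <- c(bio_order,
            names(classes[[1]]$transporter_presence),
            names(classes[[1]]$enzyme_presence))
  mat <- vapply(classes, function(cl) {
    as.integer(c(cl$role_presence[bio_order],
                 cl$transporter_presence, cl$enzyme_presence))
  }, integer(length(rows)))
  mat <- matrix(mat, nrow = length(rows),
                dimnames = list(rows, vapply(classes, `[[`, "", "genome_id")))
  union_roles <- bio_order[rowSums(mat[bio_order, , drop = FALSE]) > 0]
  routes <- kb_route_variants(kb, "COB")
  missing <- lapply(routes, function(vr)
    setdiff(vr$indispensable_role_ids, union_roles))
  names(missing) <- vapply(routes, `[[`, "", "variant_id")
  best <- which.min(vapply(missing, length, 0L))
  list(matrix = mat,
       cover = list(covered = length(missing[[best]]) == 0L,
                    best_variant = names(missing)[best],
                    bottleneck_roles = missing[[best]]))
}
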