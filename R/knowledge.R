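# Knowledge base: vitamins -> functional roles -> pathway variants.
#
# A "functional role" groups the KOs that perform the same reaction step in a
# vitamin biosynthesis pathway; a "pathway variant" is one alternative route
# to the vitamin, defined by an ordered list of roles of which a subset is
# indispensable.  Cobalamin additionally carries utilization gene lists
# (transporters, dependent enzymes) marking consumers rather than producers.

#' Vitamin codes handled by the package
#'
#' Three-letter codes for the eight B vitamins and menaquinone (K2):
#' thiamine (THI), riboflavin (RIB), niacin (NIA), pantothenate (PAN),
#' pyridoxine (PYR), biotin (BIO), folate (FOL), cobalamin (COB) and
#' menaquinone (MEN).
#'
#' @return Character vector of the nine codes.
#' @export
vitamin_codes <- function() {
  c("THI", "RIB", "NIA", "PAN", "PYR", "BIO", "FOL", "COB", "MEN")
}

#' Construct a functional role
#'
#' @param role_id Unique role identifier (unique across the knowledge base).
#' @param vitamin One of \code{\link{vitamin_codes}()}.
#' @param ko_ids Non-empty character vector of KO identifiers (\code{K#####})
#'   backing the role. Gene-symbol aliases are resolved to KO ids at curation
#'   time, so a role named after a symbol (e.g. \code{MMAB}) still stores KOs.
#' @param label Free-text description.
#' @return A list of class \code{vc_role}.
#' @export
functional_role <- function(role_id, vitamin, ko_ids, label = role_id) {
  stopifnot(is.character(role_id), length(role_id) == 1L)
  structure(
    list(role_id = role_id, vitamin = vitamin,
         ko_ids = unique(as.character(ko_ids)), label = label),
    class = "vc_role")
}

#' Construct a pathway variant
#'
#' @param variant_id Unique variant identifier.
#' @param vitamin One of \code{\link{vitamin_codes}()}.
#' @param role_ids Ordered character vector of role ids composing the route.
#' @param indispensable_role_ids Subset of \code{role_ids} that must all be
#'   present for a genome to satisfy the variant.
#' @param segment_tag Optional tag: \code{"aerobic"}, \code{"anaerobic"},
#'   \code{"post_cobyrinate"}, \code{"classical"}, \code{"futalosine"} or a
#'   free branch name. Variants tagged \code{"post_cobyrinate"} describe the
#'   shared late cobalamin segment and are not stand-alone de novo routes.
#' @return A list of class \code{vc_variant}.
#' @export
pathway_variant <- function(variant_id, vitamin, role_ids,
                            indispensable_role_ids = role_ids,
                            segment_tag = NULL) {
  structure(
    list(variant_id = variant_id, vitamin = vitamin,
         role_ids = as.character(role_ids),
         indispensable_role_ids = as.character(indispensable_role_ids),
         segment_tag = segment_tag),
    class = "vc_variant")
}

#' Assemble a knowledge base object
#'
#' Pure constructor; no validation is performed so that
#' \code{\link{validate_knowledge_base}} can be exercised on deliberately
#' broken instances.
#'
#' @param roles List of \code{\link{functional_role}} objects.
#' @param variants List of \code{\link{pathway_variant}} objects.
#' @param cobalamin_utilization List with elements \code{transporters} and
#'   \code{dependent_enzymes}, each a named list mapping a gene symbol
#'   (\code{btuB}, \code{metH}, ...) to its KO id vector. May be \code{NULL}
#'   for knowledge bases without cobalamin.
#' @param version Free-text version string recorded in outputs.
#' @return A list of class \code{vc_kb}.
#' @export
knowledge_base <- function(roles, variants, cobalamin_utilization = NULL,
                           version = "unversioned") {
  names(roles) <- vapply(roles, `[[`, "", "role_id")
  names(variants) <- vapply(variants, `[[`, "", "variant_id")
  structure(
    list(version = version, roles = roles, variants = variants,
         cobalamin_utilization = cobalamin_utilization),
    class = "vc_kb")
}

#' @export
print.vc_kb <- function(x, ...) {
  cat(sprintf("<vitacap knowledge base '%s'>\n", x$version))
  cat(sprintf("  %d roles, %d variants, %d vitamins, %d KOs\n",
              length(x$roles), length(x$variants),
              length(unique(vapply(x$roles, `[[`, "", "vitamin"))),
              length(ko_universe(x))))
  invisible(x)
}

#' Load a knowledge base from its JSON representation
#'
#' The file is a single UTF-8 JSON document with top-level keys
#' \code{version}, \code{roles}, \code{variants} and (optionally)
#' \code{cobalamin_utilization}; see the packaged default
#' (\code{system.file("extdata", "vitamin_kb.json", package = "vitacap")})
#' and the schema in
#' \code{system.file("extdata", "vitamin_kb.schema.json", package = "vitacap")}.
#' Loading is pure: the same file always yields an identical object.  The
#' loaded knowledge base is validated and loading fails, naming the offending
#' entities, if any invariant is violated.
#'
#' @param path Path to the JSON file.
#' @return A validated \code{vc_kb} object.
#' @seealso \code{\link{default_knowledge_base}},
#'   \code{\link{write_knowledge_base}}
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) {
    stop("knowledge base file not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("version", "roles", "variants")) {
    if (is.null(doc[[key]])) {
      stop("knowledge base schema violation: missing top-level key '",
           key, "' in ", path, call. = FALSE)
    }
  }
  parse_role <- function(r, i) {
    for (key in c("role_id", "vitamin", "ko_ids")) {
      if (is.null(r[[key]])) {
        stop("knowledge base schema violation: roles[", i,
             "] lacks field '", key, "'", call. = FALSE)
      }
    }
    functional_role(r$role_id, r$vitamin, unlist(r$ko_ids),
                    label = if (is.null(r$label)) r$role_id else r$label)
  }
  parse_variant <- function(v, i) {
    for (key in c("variant_id", "vitamin", "role_ids",
                  "indispensable_role_ids")) {
      if (is.null(v[[key]])) {
        stop("knowledge base schema violation: variants[", i,
             "] lacks field '", key, "'", call. = FALSE)
      }
    }
    pathway_variant(v$variant_id, v$vitamin, unlist(v$role_ids),
                    unlist(v$indispensable_role_ids),
                    segment_tag = if (is.null(v$segment_tag)) NULL
                                  else v$segment_tag)
  }
  roles <- mapply(parse_role, doc$roles, seq_along(doc$roles),
                  SIMPLIFY = FALSE)
  variants <- mapply(parse_variant, doc$variants, seq_along(doc$variants),
                     SIMPLIFY = FALSE)
  util <- NULL
  if (!is.null(doc$cobalamin_utilization)) {
    util <- list(
      transporters = lapply(doc$cobalamin_utilization$transporters,
                            function(x) unique(unlist(x))),
      dependent_enzymes = lapply(doc$cobalamin_utilization$dependent_enzymes,
                                 function(x) unique(unlist(x))))
  }
  kb <- knowledge_base(roles, variants, util, version = doc$version)
  violations <- validate_knowledge_base(kb)
  if (length(violations)) {
    stop("invalid knowledge base '", path, "':\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  kb
}

#' Serialize a knowledge base to JSON
#'
#' Round-trips through \code{\link{load_knowledge_base}} without loss.
#'
#' @param kb A \code{vc_kb} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  doc <- list(
    version = kb$version,
    roles = lapply(unname(kb$roles), function(r) {
      list(role_id = r$role_id, vitamin = r$vitamin,
           ko_ids = as.list(r$ko_ids), label = r$label)
    }),
    variants = lapply(unname(kb$variants), function(v) {
      out <- list(variant_id = v$variant_id, vitamin = v$vitamin,
                  role_ids = as.list(v$role_ids),
                  indispensable_role_ids = as.list(v$indispensable_role_ids))
      if (!is.null(v$segment_tag)) out$segment_tag <- v$segment_tag
      out
    }))
  if (!is.null(kb$cobalamin_utilization)) {
    doc$cobalamin_utilization <- list(
      transporters = lapply(kb$cobalamin_utilization$transporters, as.list),
      dependent_enzymes = lapply(kb$cobalamin_utilization$dependent_enzymes,
                                 as.list))
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' The packaged default knowledge base
#'
#' A versioned curation of the B/K2 biosynthesis genes discussed in the
#' package vignette: nine vitamins, branch structure for thiamine
#' (thiH/thiO), niacin (NaMNAT/NMNAT), pyridoxine, biotin (bioW and
#' bioC-bioZ/G/H/K), menaquinone (classical/futalosine), and the
#' tri-segmented cobalamin pathway (anaerobic, aerobic, post-cobyrinate
#' a,c-diamide) plus cobalamin transporter and dependent-enzyme lists.
#' KO assignments are a best-effort curation; analyses that need exact
#' correspondence with a specific KEGG release should load their own file.
#'
#' @return A validated \code{vc_kb} object.
#' @export
default_knowledge_base <- function() {
  load_knowledge_base(system.file("extdata", "vitamin_kb.json",
                                  package = "vitacap", mustWork = TRUE))
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: non-empty KO sets, role-id uniqueness,
#' within-vitamin KO disjointness across roles, resolvable role references,
#' non-empty indispensable sets contained in their variant's roles, at least
#' one variant per vitamin, the tri-segment structure of cobalamin, and
#' disjointness of the utilization lists from cobalamin biosynthesis KOs.
#'
#' @param kb A \code{vc_kb} object.
#' @return Character vector of human-readable violations; empty iff valid.
#'   Violations are data, not errors: broken knowledge bases are reported,
#'   not thrown.
#' @export
validate_knowledge_base <- function(kb) {
  v <- character()
  role_ids <- vapply(kb$roles, `[[`, "", "role_id")
  if (anyDuplicated(role_ids)) {
    v <- c(v, paste0("duplicate role_id: ",
                     paste(unique(role_ids[duplicated(role_ids)]),
                           collapse = ", ")))
  }
  for (r in kb$roles) {
    if (length(r$ko_ids) == 0L) {
      v <- c(v, paste0("role ", r$role_id, " has an empty ko_ids set"))
    }
    if (!r$vitamin %in% vitamin_codes()) {
      v <- c(v, paste0("role ", r$role_id, " has unknown vitamin '",
                       r$vitamin, "'"))
    }
  }
  # within one vitamin a KO may back at most one role
  by_vit <- split(kb$roles, vapply(kb$roles, `[[`, "", "vitamin"))
  for (vit in names(by_vit)) {
    kos <- unlist(lapply(by_vit[[vit]], `[[`, "ko_ids"))
    dup <- unique(kos[duplicated(kos)])
    for (ko in dup) {
      offenders <- vapply(by_vit[[vit]], `[[`, "", "role_id")[
        vapply(by_vit[[vit]], function(r) ko %in% r$ko_ids, NA)]
      v <- c(v, paste0("KO ", ko, " appears in multiple ", vit, " roles: ",
                       paste(offenders, collapse = ", ")))
    }
  }
  vit_with_variant <- character()
  for (vr in kb$variants) {
    missing <- setdiff(vr$role_ids, role_ids)
    if (length(missing)) {
      v <- c(v, paste0("variant ", vr$variant_id,
                       " references unknown role(s): ",
                       paste(missing, collapse = ", ")))
    }
    if (length(vr$indispensable_role_ids) == 0L) {
      v <- c(v, paste0("variant ", vr$variant_id,
                       " has no indispensable roles"))
    }
    stray <- setdiff(vr$indispensable_role_ids, vr$role_ids)
    if (length(stray)) {
      v <- c(v, paste0("variant ", vr$variant_id,
                       " marks roles indispensable that are not in role_ids: ",
                       paste(stray, collapse = ", ")))
    }
    vit_with_variant <- c(vit_with_variant, vr$vitamin)
  }
  for (vit in unique(vapply(kb$roles, `[[`, "", "vitamin"))) {
    if (!vit %in% vit_with_variant) {
      v <- c(v, paste0("vitamin ", vit, " has roles but no pathway variant"))
    }
  }
  if ("COB" %in% vit_with_variant) {
    tags <- unlist(lapply(kb$variants, function(x)
      if (identical(x$vitamin, "COB") && !is.null(x$segment_tag))
        x$segment_tag else NULL))
    for (needed in c("anaerobic", "aerobic", "post_cobyrinate")) {
      if (!needed %in% tags) {
        v <- c(v, paste0("cobalamin lacks a variant tagged '", needed, "'"))
      }
    }
    if (is.null(kb$cobalamin_utilization)) {
      v <- c(v, "cobalamin present but cobalamin_utilization lists missing")
    }
  }
  if (!is.null(kb$cobalamin_utilization)) {
    tr <- kb$cobalamin_utilization$transporters
    en <- kb$cobalamin_utilization$dependent_enzymes
    if (length(tr) == 0L) v <- c(v, "empty cobalamin transporter list")
    if (length(en) == 0L) v <- c(v, "empty cobalamin dependent-enzyme list")
    cob_kos <- ko_universe_unsafe(kb, "COB")
    overlap <- intersect(unlist(c(tr, en)), cob_kos)
    if (length(overlap)) {
      v <- c(v, paste0("utilization KO(s) overlap COB biosynthesis roles: ",
                       paste(overlap, collapse = ", ")))
    }
  }
  v
}

# ko_universe without the vitamin-existence check (used during validation)
ko_universe_unsafe <- function(kb, vitamin = NULL) {
  roles <- kb$roles
  if (!is.null(vitamin)) {
    roles <- roles[vapply(roles, function(r) r$vitamin %in% vitamin, NA)]
  }
  unique(unlist(lapply(roles, `[[`, "ko_ids"), use.names = FALSE))
}

#' KO universe of a knowledge base
#'
#' The union of KO ids over all roles, optionally restricted to one vitamin.
#' This set defines which catalog genes count as "vitamin genes" during
#' profiling.
#'
#' @param kb A \code{vc_kb} object.
#' @param vitamin Optional vitamin code.
#' @return Character vector of KO ids (no particular order guaranteed beyond
#'   determinism for a fixed knowledge base).
#' @export
ko_universe <- function(kb, vitamin = NULL) {
  if (!is.null(vitamin)) {
    known <- unique(vapply(kb$roles, `[[`, "", "vitamin"))
    if (!vitamin %in% known) {
      stop("unknown vitamin id: ", vitamin, call. = FALSE)
    }
  }
  kos <- ko_universe_unsafe(kb, vitamin)
  if (is.null(kos)) character() else kos
}

# --- internal lookups used by capability and profiling ---------------------

kb_vitamins <- function(kb) {
  unique(vapply(kb$variants, `[[`, "", "vitamin"))
}

# de novo route variants of a vitamin (post_cobyrinate segment variants are a
# shared tail, not a stand-alone route)
kb_route_variants <- function(kb, vitamin) {
  Filter(function(v) {
    identical(v$vitamin, vitamin) &&
      (is.null(v$segment_tag) || v$segment_tag != "post_cobyrinate")
  }, kb$variants)
}

kb_variants_of <- function(kb, vitamin) {
  Filter(function(v) identical(v$vitamin, vitamin), kb$variants)
}

# roles of the three cobalamin segments; the route variants bundle the
# post-cobyrinate tail, so segment-only membership is derived by difference
cob_segment_roles <- function(kb) {
  vars <- kb_variants_of(kb, "COB")
  tag_of <- function(v) if (is.null(v$segment_tag)) "" else v$segment_tag
  post <- unique(unlist(lapply(Filter(function(v) tag_of(v) == "post_cobyrinate",
                                      vars), `[[`, "role_ids")))
  seg <- function(tag) {
    unique(unlist(lapply(Filter(function(v) tag_of(v) == tag, vars),
                         `[[`, "role_ids")))
  }
  list(anaerobic = setdiff(seg("anaerobic"), post),
       aerobic = setdiff(seg("aerobic"), post),
       post_cobyrinate = post)
}
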