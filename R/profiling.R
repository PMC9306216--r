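# Metagenome abundance profiling: gene read counts -> TPM -> KO -> functional
# role -> pathway -> taxon-attributed profiles.
#
# Profiles are plain numeric matrices (entities x samples) carrying a
# "vc_level" attribute and, where relevant, the knowledge-base version and
# taxonomic rank, so they can be written/read as ordinary TSV.

new_profile <- function(mat, level, kb_version = NULL, rank = NULL) {
  attr(mat, "vc_level") <- level
  if (!is.null(kb_version)) attr(mat, "vc_kb_version") <- kb_version
  if (!is.null(rank)) attr(mat, "vc_rank") <- rank
  mat
}

check_catalog <- function(catalog) {
  needed <- c("gene_id", "length_bp")
  if (!all(needed %in% names(catalog))) {
    stop("gene catalog must have columns gene_id and length_bp",
         call. = FALSE)
  }
  if (anyDuplicated(catalog$gene_id)) {
    stop("duplicate gene_id in catalog: ",
         paste(unique(catalog$gene_id[duplicated(catalog$gene_id)])[1:5],
               collapse = ", "), call. = FALSE)
  }
  if (any(catalog$length_bp <= 0)) {
    stop("non-positive gene length for: ",
         paste(catalog$gene_id[catalog$length_bp <= 0][1:5], collapse = ", "),
         call. = FALSE)
  }
  invisible(catalog)
}

#' Convert gene read counts to TPM
#'
#' Transcripts-per-million normalisation over the whole gene catalog:
#' \code{tpm(g,s) = (c(g,s)/L(g)) / sum_h(c(h,s)/L(h)) * 1e6}.  Every sample
#' column with any positive count sums to exactly one million (up to floating
#' precision); all-zero columns stay all-zero rather than erroring, so
#' partial runs pass through.  The denominator covers the full catalog, not
#' just vitamin genes — subsetting to a KO universe happens downstream, which
#' matters for absolute values and mirrors profiling a whole gene catalog
#' before selecting the pathway genes.
#'
#' @param counts Non-negative integer matrix, genes x samples, rownames =
#'   gene ids.
#' @param catalog data.frame with at least \code{gene_id} and
#'   \code{length_bp}; every counted gene must have a catalog length.
#' @return Numeric matrix of TPM values with level attribute \code{"gene"}.
#' @export
compute_tpm <- function(counts, catalog) {
  check_catalog(catalog)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts matrix needs gene ids as rownames", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative read counts", call. = FALSE)
  missing <- setdiff(rownames(counts), catalog$gene_id)
  if (length(missing)) {
    stop("counted gene(s) absent from catalog: ",
         paste(missing[seq_len(min(5, length(missing)))], collapse = ", "),
         call. = FALSE)
  }
  len <- catalog$length_bp[match(rownames(counts), catalog$gene_id)]
  rate <- counts / len
  denom <- colSums(rate)
  scale <- ifelse(denom > 0, 1e6 / denom, 0)
  tpm <- sweep(rate, 2, scale, `*`)
  new_profile(tpm, "gene")
}

#' Aggregate gene TPM to KO abundance
#'
#' Sums the TPM of all genes annotated to each KO; genes without a KO
#' annotation (empty \code{ko_id}) contribute to no KO.
#'
#' @param tpm Gene-level TPM matrix from \code{\link{compute_tpm}}.
#' @param catalog Gene catalog with a \code{ko_id} column.
#' @return KO x samples profile matrix (level \code{"KO"}).
#' @export
aggregate_ko <- function(tpm, catalog) {
  ko <- as.character(catalog$ko_id[match(rownames(tpm), catalog$gene_id)])
  keep <- !is.na(ko) & ko != ""
  if (!any(keep)) {
    out <- matrix(0, 0, ncol(tpm), dimnames = list(NULL, colnames(tpm)))
    return(new_profile(out, "KO"))
  }
  out <- rowsum(tpm[keep, , drop = FALSE], group = ko[keep])
  new_profile(as.matrix(out), "KO")
}

#' Aggregate KO abundance to functional roles
#'
#' Role abundance = sum of the abundances of the role's KOs (KOs absent from
#' the profile contribute zero).
#'
#' @param ko_profile KO-level profile from \code{\link{aggregate_ko}}.
#' @param kb A validated knowledge base.
#' @return Role x samples profile matrix (level \code{"role"}).
#' @export
aggregate_role <- function(ko_profile, kb) {
  out <- entity_sums(names(kb$roles), function(rid) {
    hit <- intersect(kb$roles[[rid]]$ko_ids, rownames(ko_profile))
    if (length(hit)) colSums(ko_profile[hit, , drop = FALSE])
    else rep(0, ncol(ko_profile))
  }, ko_profile)
  new_profile(out, "role", kb_version = kb$version)
}

# rows = entities, columns = samples; robust to single-sample profiles
entity_sums <- function(entities, f, profile) {
  out <- matrix(0, length(entities), ncol(profile),
                dimnames = list(entities, colnames(profile)))
  for (i in seq_along(entities)) out[i, ] <- f(entities[i])
  out
}

#' Pathway (per-vitamin) abundance
#'
#' The abundance of a vitamin's biosynthesis pathway is the sum of its KO
#' universe's abundances; a KO referenced by several variants of the vitamin
#' is counted once (the pathway is a KO set).
#'
#' @param ko_profile KO-level profile from \code{\link{aggregate_ko}}.
#' @param kb A validated knowledge base.
#' @return Vitamin x samples profile matrix (level \code{"pathway"}).
#' @export
pathway_abundance <- function(ko_profile, kb) {
  out <- entity_sums(kb_vitamins(kb), function(vit) {
    hit <- intersect(ko_universe(kb, vit), rownames(ko_profile))
    if (length(hit)) colSums(ko_profile[hit, , drop = FALSE])
    else rep(0, ncol(ko_profile))
  }, ko_profile)
  new_profile(out, "pathway", kb_version = kb$version)
}

#' Taxon attribution of a vitamin's pathway abundance
#'
#' For one vitamin, sums the TPM of the vitamin's genes per taxon at the
#' requested rank. Genes lacking the rank label fall into an explicit
#' \code{"unassigned"} bucket, so per-sample taxon totals always equal the
#' vitamin's pathway abundance.
#'
#' @param tpm Gene-level TPM matrix.
#' @param catalog Gene catalog with \code{ko_id} and the rank column.
#' @param kb A validated knowledge base.
#' @param vitamin Vitamin code.
#' @param rank \code{"phylum"} or \code{"genus"}.
#' @return Taxon x samples profile matrix (level \code{"taxon"}).
#' @export
taxon_breakdown <- function(tpm, catalog, kb, vitamin,
                            rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  if (!rank %in% names(catalog)) {
    stop("catalog lacks a '", rank, "' column", call. = FALSE)
  }
  kos <- ko_universe(kb, vitamin)  # errors on unknown vitamin
  idx <- match(rownames(tpm), catalog$gene_id)
  ko <- as.character(catalog$ko_id[idx])
  keep <- !is.na(ko) & ko %in% kos
  taxa <- as.character(catalog[[rank]][idx])
  taxa[is.na(taxa) | taxa == ""] <- "unassigned"
  if (!any(keep)) {
    out <- matrix(0, 0, ncol(tpm), dimnames = list(NULL, colnames(tpm)))
    return(new_profile(out, "taxon", kb_version = kb$version, rank = rank))
  }
  out <- rowsum(tpm[keep, , drop = FALSE], group = taxa[keep])
  new_profile(as.matrix(out), "taxon", kb_version = kb$version, rank = rank)
}
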