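# Pipeline orchestration behind the command-line entry point.

default_thresholds <- function() {
  list(min_completeness = 90, max_contamination = 5, prevalence = 0.9,
       alpha = 0.05, lda_threshold = 3, n_permutations = 1000)
}

check_thresholds <- function(th) {
  if (th$min_completeness < 0 || th$min_completeness > 100)
    stop("min_completeness must lie in [0, 100]", call. = FALSE)
  if (th$max_contamination < 0 || th$max_contamination > 100)
    stop("max_contamination must lie in [0, 100]", call. = FALSE)
  if (th$prevalence <= 0 || th$prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (th$alpha <= 0 || th$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (th$lda_threshold < 0)
    stop("lda_threshold must be non-negative", call. = FALSE)
  invisible(th)
}

#' Run one pipeline stage
#'
#' Orchestrates the module pipeline for one subcommand and writes its output
#' files plus a machine-readable manifest (\code{manifest.json} with input
#' checksums, parameters and package version) into \code{config$out}.
#' Re-running with identical inputs and seed produces byte-identical
#' outputs.
#'
#' Subcommands and their required config fields:
#' \describe{
#'   \item{kb-validate}{\code{kb}: path. Writes \code{violations.txt};
#'     errors (non-zero exit from the CLI) if the base is invalid.}
#'   \item{simulate}{\code{preset} ("diet"/"region"), \code{seed}. Writes a
#'     full dataset (see \code{\link{write_dataset}}).}
#'   \item{predict}{\code{kb}, \code{annotations}, \code{metadata} paths.
#'     Quality-filters, then writes \code{capability.tsv},
#'     \code{cobalamin_class.tsv}, \code{rejected_genomes.txt}.}
#'   \item{profile}{\code{kb}, \code{catalog}, \code{counts} paths. Writes
#'     \code{profile_ko.tsv}, \code{profile_role.tsv},
#'     \code{profile_pathway.tsv}, \code{profile_taxon_phylum.tsv}.}
#'   \item{compare}{\code{profiles} (pathway-level TSV),
#'     \code{sample_metadata} path. Writes \code{distance.tsv},
#'     \code{pcoa_coords.tsv}, \code{amova.json}, \code{enrichment.tsv}.}
#'   \item{enrich}{\code{features} (feature x sample TSV),
#'     \code{sample_metadata}. Writes \code{lda.tsv}.}
#' }
#'
#' @param config Named list: \code{subcommand}, input paths as above,
#'   \code{out} directory, \code{seed}, and optional overrides of the
#'   default thresholds (\code{min_completeness} 90,
#'   \code{max_contamination} 5, \code{prevalence} 0.9, \code{alpha} 0.05,
#'   \code{lda_threshold} 3, \code{n_permutations} 1000).
#' @return The output directory, invisibly.
#' @export
vc_run <- function(config) {
  if (is.null(config$subcommand)) stop("config$subcommand is required",
                                       call. = FALSE)
  if (is.null(config$out)) stop("config$out is required", call. = FALSE)
  th <- utils::modifyList(default_thresholds(),
                          config[intersect(names(config),
                                           names(default_thresholds()))])
  check_thresholds(th)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  need <- function(field) {
    if (is.null(config[[field]])) {
      stop("missing required config field '", field, "' for subcommand ",
           config$subcommand, call. = FALSE)
    }
    config[[field]]
  }

  switch(config$subcommand,
    "kb-validate" = {
      kb <- load_knowledge_base(need("kb"))  # errors if invalid
      writeLines(character(), file.path(out, "violations.txt"))
    },
    "simulate" = {
      ds <- simulate_preset(need("preset"), seed = seed)
      write_dataset(ds, out)
    },
    "predict" = {
      kb <- load_knowledge_base(need("kb"))
      genomes <- genomes_from_tables(
        read_genome_annotations(need("annotations")),
        read_genome_metadata(need("metadata")))
      qf <- quality_filter(genomes, th$min_completeness,
                           th$max_contamination)
      write_tsv(predict_capability_all(qf$kept, kb),
                file.path(out, "capability.tsv"))
      if ("COB" %in% kb_vitamins(kb)) {
        write_tsv(classify_cobalamin_all(qf$kept, kb),
                  file.path(out, "cobalamin_class.tsv"))
      }
      writeLines(vapply(qf$rejected, `[[`, "", "genome_id"),
                 file.path(out, "rejected_genomes.txt"))
    },
    "profile" = {
      kb <- load_knowledge_base(need("kb"))
      catalog <- read_gene_catalog(need("catalog"))
      counts <- read_counts(need("counts"))
      tpm <- compute_tpm(counts, catalog)
      kop <- aggregate_ko(tpm, catalog)
      write_matrix_tsv(kop, file.path(out, "profile_ko.tsv"), "ko_id")
      write_matrix_tsv(aggregate_role(kop, kb),
                       file.path(out, "profile_role.tsv"), "role_id")
      path_prof <- pathway_abundance(kop, kb)
      write_matrix_tsv(path_prof, file.path(out, "profile_pathway.tsv"),
                       "vitamin")
      if ("phylum" %in% names(catalog)) {
        tax <- do.call(rbind, lapply(kb_vitamins(kb), function(vit) {
          tb <- taxon_breakdown(tpm, catalog, kb, vit, "phylum")
          if (nrow(tb) == 0) return(NULL)
          rownames(tb) <- paste(vit, rownames(tb), sep = "|")
          tb
        }))
        if (!is.null(tax)) {
          write_matrix_tsv(tax, file.path(out, "profile_taxon_phylum.tsv"),
                           "vitamin|phylum")
        }
      }
    },
    "compare" = {
      prof <- read_matrix_tsv(need("profiles"))
      meta <- read_tsv(need("sample_metadata"))
      groups <- setNames(meta$group, meta$sample_id)[colnames(prof)]
      d <- bray_curtis(prof)
      write_matrix_tsv(d, file.path(out, "distance.tsv"), "sample_id")
      ord <- pcoa(d, k = 2)
      write_matrix_tsv(ord$coordinates, file.path(out, "pcoa_coords.tsv"),
                       "sample_id")
      am <- amova(d, groups, n_permutations = th$n_permutations,
                  seed = seed)
      writeLines(jsonlite::toJSON(unclass(am), auto_unbox = TRUE,
                                  pretty = TRUE, digits = NA, null = "null"),
                 file.path(out, "amova.json"), useBytes = TRUE)
      enr <- differential_enrichment(prof, groups, alpha = th$alpha)
      write_tsv(enr, file.path(out, "enrichment.tsv"))
    },
    "enrich" = {
      feats <- read_matrix_tsv(need("features"))
      meta <- read_tsv(need("sample_metadata"))
      groups <- setNames(meta$group, meta$sample_id)[colnames(feats)]
      lda <- lda_effect_size(feats, groups, threshold = th$lda_threshold,
                             alpha = th$alpha, seed = seed)
      write_tsv(lda, file.path(out, "lda.tsv"))
    },
    stop("unknown subcommand: ", config$subcommand, call. = FALSE)
  )
  params <- c(list(subcommand = config$subcommand, seed = seed), th,
              lapply(config[intersect(names(config),
                                      c("kb", "annotations", "metadata",
                                        "catalog", "counts", "profiles",
                                        "features", "sample_metadata",
                                        "preset"))], as.character))
  inputs <- unlist(config[intersect(names(config),
                                    c("kb", "annotations", "metadata",
                                      "catalog", "counts", "profiles",
                                      "features", "sample_metadata"))])
  if (length(inputs)) {
    params$input_md5 <- as.list(setNames(unname(tools::md5sum(inputs)),
                                         basename(inputs)))
  }
  write_run_manifest(out, params)
  invisible(out)
}
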