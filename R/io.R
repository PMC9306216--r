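# Shared readers/writers: TSV dialects for genome annotations, gene
# catalogs, count matrices and profiles, plus JSON run manifests.
# All writers emit UTF-8, LF line endings, tab delimiters, and exactly the
# documented headers, so repeated runs are byte-identical.

#' Write a data frame as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             ...)
}

#' Read genome KO annotations
#'
#' Long-format TSV with header \code{genome_id<TAB>ko_id}, one row per
#' (genome, KO) pair; duplicate pairs collapse.
#'
#' @param path Annotation TSV path.
#' @return Named list: genome id -> character vector of KO ids.
#' @export
read_genome_annotations <- function(path) {
  df <- read_tsv(path)
  if (!all(c("genome_id", "ko_id") %in% names(df))) {
    stop("annotation file needs columns genome_id and ko_id: ", path,
         call. = FALSE)
  }
  lapply(split(df$ko_id, df$genome_id), unique)
}

#' Read genome metadata
#'
#' TSV with header \code{genome_id, completeness, contamination, domain,
#' phylum, class, order, family, genus, assembly_size_bp, source_region}
#' (taxonomy and source columns may be empty).
#'
#' @param path Metadata TSV path.
#' @return data.frame.
#' @export
read_genome_metadata <- function(path) {
  df <- read_tsv(path)
  needed <- c("genome_id", "completeness", "contamination",
              "assembly_size_bp")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("genome metadata lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Assemble genome annotations from the two genome tables
#'
#' @param annotations Named list from \code{\link{read_genome_annotations}}.
#' @param metadata data.frame from \code{\link{read_genome_metadata}}.
#' @return List of \code{\link{genome_annotation}} objects, in metadata
#'   order; genomes without annotation rows get empty KO sets.
#' @export
genomes_from_tables <- function(annotations, metadata) {
  ranks <- intersect(c("domain", "phylum", "class", "order", "family",
                       "genus"), names(metadata))
  lapply(seq_len(nrow(metadata)), function(i) {
    row <- metadata[i, ]
    kos <- annotations[[row$genome_id]]
    tax <- vapply(ranks, function(r) as.character(row[[r]]), "")
    genome_annotation(
      row$genome_id, ko_set = if (is.null(kos)) character() else kos,
      completeness = row$completeness, contamination = row$contamination,
      taxonomy = tax, assembly_size = row$assembly_size_bp,
      source_region = if ("source_region" %in% names(metadata))
        row$source_region else NULL)
  })
}

#' Write genome tables for a list of genome annotations
#'
#' @param genomes List of \code{vc_genome}.
#' @param annotations_path,metadata_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
genomes_to_tables <- function(genomes, annotations_path, metadata_path) {
  ann <- do.call(rbind, lapply(genomes, function(g) {
    if (length(g$ko_set) == 0L) return(NULL)
    data.frame(genome_id = g$genome_id, ko_id = g$ko_set,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(genome_id = character(), ko_id = character())
  }
  write_tsv(ann, annotations_path)
  tax_field <- function(g, r) {
    v <- g$taxonomy[r]
    if (is.null(v) || is.na(v)) "" else as.character(v)
  }
  meta <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome_id = g$genome_id,
               completeness = g$completeness,
               contamination = g$contamination,
               domain = tax_field(g, "domain"),
               phylum = tax_field(g, "phylum"),
               class = tax_field(g, "class"),
               order = tax_field(g, "order"),
               family = tax_field(g, "family"),
               genus = tax_field(g, "genus"),
               assembly_size_bp = g$assembly_size,
               source_region = if (is.null(g$source_region)) ""
                               else g$source_region,
               stringsAsFactors = FALSE)
  }))
  write_tsv(meta, metadata_path)
  invisible(c(annotations_path, metadata_path))
}

#' Read a gene catalog
#'
#' TSV with header \code{gene_id, length_bp, ko_id, phylum, genus}; empty
#' strings mean unannotated.
#'
#' @param path Catalog TSV path.
#' @return data.frame.
#' @export
read_gene_catalog <- function(path) {
  df <- read_tsv(path, colClasses = c(gene_id = "character",
                                      ko_id = "character"))
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    stop("gene catalog needs columns gene_id and length_bp: ", path,
         call. = FALSE)
  }
  check_catalog(df)
}

#' Read a count matrix
#'
#' Wide TSV (first column \code{gene_id}, remaining columns samples) or the
#' sparse triplet dialect \code{gene_id, sample_id, count} (detected from
#' the header).
#'
#' @param path Counts TSV path.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (identical(names(df), c("gene_id", "sample_id", "count"))) {
    genes <- unique(df$gene_id); samples <- unique(df$sample_id)
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(df$gene_id, df$sample_id)] <- as.integer(df$count)
    return(m)
  }
  if (names(df)[1] != "gene_id") {
    stop("counts file must start with a gene_id column: ", path,
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Write a matrix with an id column as TSV
#'
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_name Name of the first (id) column.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "entity_id") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' Read a profile or matrix TSV written by \code{\link{write_matrix_tsv}}
#'
#' @param path TSV path.
#' @return Numeric matrix with the first column as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a run manifest
#'
#' Records the package version, parameters, seed and md5 checksums of every
#' file in the output directory, sufficient to reproduce and audit a run.
#'
#' @param out_dir Output directory.
#' @param params Named list of run parameters (seed included).
#' @return Manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, params) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "vitacap",
    version = as.character(utils::packageVersion("vitacap")),
    parameters = params,
    files = as.list(setNames(unname(sums), files)))
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits every table in the dialect the downstream stages consume:
#' \code{kb.json}, \code{annotations.tsv}, \code{genome_metadata.tsv},
#' \code{catalog.tsv}, \code{counts.tsv}, \code{sample_metadata.tsv} and
#' \code{truth.json}.
#'
#' @param dataset A \code{vc_dataset} from \code{\link{simulate_community}}
#'   or \code{\link{simulate_preset}}.
#' @param dir Output directory (created if needed).
#' @param truth Optional extra planted-truth list (e.g. genome capabilities
#'   from \code{\link{simulate_genomes}}) merged into \code{truth.json}.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_knowledge_base(dataset$kb, file.path(dir, "kb.json"))
  genomes_to_tables(dataset$genomes, file.path(dir, "annotations.tsv"),
                    file.path(dir, "genome_metadata.tsv"))
  write_tsv(dataset$catalog[, c("gene_id", "length_bp", "ko_id", "phylum",
                                "genus")],
            file.path(dir, "catalog.tsv"))
  write_matrix_tsv(dataset$counts, file.path(dir, "counts.tsv"),
                   id_name = "gene_id")
  write_tsv(dataset$sample_metadata, file.path(dir, "sample_metadata.tsv"))
  tr <- dataset$truth
  if (!is.null(truth)) tr <- c(tr, truth)
  tr$fold_design <- as.data.frame(tr$fold_design)
  tr$expected_pathway_tpm <- as.data.frame(tr$expected_pathway_tpm)
  writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, dataframe = "columns",
                              na = "null"),
             file.path(dir, "truth.json"), useBytes = TRUE)
  invisible(dir)
}
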