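# File formats: GMT gene-set collections (with a TSG-A/OG-I class label in
# the description field), RNK rank files, TSV matrices and tables. All
# parsers are round-trip safe with the corresponding writers.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (nonempty, unique names).
#' @param class named character vector of class labels ("TSG-A"/"OG-I"),
#'   aligned with `sets`; unlabeled sets get NA.
#' @param description optional named character vector of descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, class = NULL, description = NULL) {
  if (length(sets) == 0) stop("empty collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  if (any(lengths(sets) == 0)) stop("every set must be nonempty")
  nms <- names(sets)
  cls <- stats::setNames(rep(NA_character_, length(sets)), nms)
  if (!is.null(class)) cls[names(class)] <- class
  desc <- stats::setNames(rep("", length(sets)), nms)
  if (!is.null(description)) desc[names(description)] <- description
  structure(list(sets = sets, class = cls, description = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  tab <- table(x$class, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Parse a GMT gene-set file
#'
#' Tab-separated: set name, description, members... A description equal to
#' "TSG-A" or "OG-I" is read as the set's class label (the dialect
#' [write_gmt()] emits). Lines with fewer than one member are rejected
#' with their line number.
#'
#' @param path GMT path.
#' @return a [gene_set_collection()].
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); cls <- character(0); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has no members", i))
    nm <- fields[1]
    if (nm %in% names(sets))
      stop(sprintf("GMT line %d: duplicate set name '%s'", i, nm))
    sets[[nm]] <- fields[-(1:2)]
    cls[nm] <- if (fields[2] %in% c("TSG-A", "OG-I")) fields[2]
    else NA_character_
    desc[nm] <- fields[2]
  }
  gene_set_collection(sets, class = cls, description = desc)
}

#' Write a gene-set collection as GMT
#'
#' The class label (when present) is written in the description field.
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    d <- collection$class[nm]
    if (is.na(d)) d <- collection$description[nm]
    if (is.na(d) || d == "") d <- "na"
    paste(c(nm, d, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse an RNK rank file
#'
#' Two tab-separated columns (gene, score), no header. Non-numeric scores
#' are rejected with their line number. The result is re-sorted through
#' [make_rank_file()].
#'
#' @param path RNK path.
#' @return a `ranked_list`.
#' @export
parse_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene", "score"),
                          colClasses = c("character", "character"))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score))
  if (length(bad) > 0)
    stop("non-numeric score at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  make_rank_file(stats::setNames(score, df$gene))
}

#' Write a ranked list as RNK
#'
#' @param ranked a `ranked_list`.
#' @param path output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix
#'
#' First column holds row identifiers; remaining columns are numeric.
#'
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a matrix as TSV
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the identifier column, default "id".
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all synthetic inputs to a directory
#'
#' Generates the methylation, expression, gene-set and cohort data for a
#' configuration and writes them in the same TSV/GMT formats the pipeline
#' reads, together with a YAML manifest recording the configuration and
#' the ground-truth file paths. The cohort is generated against the true
#' planted repressed genes.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return path to the manifest (invisibly); the manifest lists every file.
#' @export
generate_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meth <- make_methylation_dataset(cfg)
  expr <- make_expression_dataset(cfg, meth$truth)
  gs <- make_gene_sets(cfg, expr$truth)
  truth <- gs$truth
  cohort <- make_cohort(cfg, truth$repressed_gene_ids)
  truth$true_patient_score <- cohort$true_score

  p <- function(f) file.path(dir, f)
  write_matrix_tsv(meth$M, p("intensity_methylated.tsv"), "probe_id")
  write_matrix_tsv(meth$U, p("intensity_unmethylated.tsv"), "probe_id")
  write_matrix_tsv(meth$detection_p, p("detection_p.tsv"), "probe_id")
  write_table_tsv(meth$annotation, p("probe_annotation.tsv"))
  write_matrix_tsv(expr$tpm, p("expression_tpm.tsv"), "gene")
  write_gmt(gs$sets, p("gene_sets.gmt"))
  write_matrix_tsv(cohort$expr, p("cohort_expression.tsv"), "gene")
  write_table_tsv(cohort$clinical, p("cohort_clinical.tsv"))
  truth_json <- truth
  truth_json$true_patient_score <- as.list(truth_json$true_patient_score)
  jsonlite::write_json(truth_json, p("ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)

  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    condition = as.character(meth$condition),
    files = list(
      intensity_methylated = "intensity_methylated.tsv",
      intensity_unmethylated = "intensity_unmethylated.tsv",
      detection_p = "detection_p.tsv",
      probe_annotation = "probe_annotation.tsv",
      expression_tpm = "expression_tpm.tsv",
      gene_sets = "gene_sets.gmt",
      cohort_expression = "cohort_expression.tsv",
      cohort_clinical = "cohort_clinical.tsv",
      ground_truth = "ground_truth.json"))
  manifest$config$region_mix <- as.list(cfg$region_mix)
  manifest$config <- lapply(manifest$config, function(v)
    if (is.factor(v)) as.character(v) else v)
  manifest_path <- p("manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
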