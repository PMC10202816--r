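# readers and writers for the plain-text interchange formats

#' Read and write expression matrices as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#'
#' @param path file path.
#' @return `read_expression_tsv()`: numeric matrix genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  assert_matrix_named(m, basename(path))
}

#' @rdname read_expression_tsv
#' @param expr matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene signature files
#'
#' One gene per line, with a `# name: <signature name>` header line.
#'
#' @param path file path.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  header <- grep("^#\\s*name:", lines, value = TRUE)
  name <- if (length(header)) {
    trimws(sub("^#\\s*name:\\s*", "", header[1]))
  } else {
    basename(path)
  }
  genes <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  gene_signature(name, genes)
}

#' @rdname read_signature
#' @param sig a [gene_signature()].
#' @export
write_signature <- function(sig, path) {
  writeLines(c(sprintf("# name: %s", sig$name), sig$genes), path)
  invisible(path)
}

#' Read a clone table as a repertoire
#'
#' Tab-separated clone tables with immunoSEQ-export-style headers are
#' accepted: the sequence column may be named `sequence`, `nucleotide` or
#' `rearrangement`; the count column `templates`, `count` or
#' `templates (count)`; the productive flag either a logical `productive`
#' column or a `frame_type`/`sequenceStatus` column whose value `In` /
#' `In-frame` marks productive clones.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name.
#' @param assay passed to [repertoire()].
#' @return A [repertoire()].
#' @export
read_clone_tsv <- function(path, sample_id = basename(path),
                           assay = "dna-targeted") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) NULL else df[[i]]
  }
  seqs <- pick(c("sequence", "nucleotide", "rearrangement", "clone_id"))
  counts <- pick(c("templates", "count", "templates (count)", "reads"))
  if (is.null(seqs) || is.null(counts)) {
    stop_("clone table needs a sequence column and a template-count column")
  }
  prod <- pick(c("productive"))
  if (is.null(prod)) {
    frame <- pick(c("frame_type", "sequencestatus", "frame type"))
    prod <- if (is.null(frame)) {
      rep(TRUE, nrow(df))
    } else {
      tolower(frame) %in% c("in", "in-frame", "inframe")
    }
  } else {
    prod <- as.logical(prod) | tolower(as.character(prod)) %in% c("true", "yes", "1")
  }
  repertoire(sample_id, seqs, counts, prod, assay = assay)
}

#' @rdname read_clone_tsv
#' @param rep a [repertoire()] to write.
#' @export
write_clone_tsv <- function(rep, path) {
  df <- rep$clones[, c("clone_id", "templates", "productive")]
  names(df) <- c("sequence", "templates", "productive")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write abundance tables as TSV
#'
#' Samples in rows (first column `sample`), taxa in columns.
#'
#' @param path file path.
#' @return Numeric matrix samples x taxa.
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_abundance_tsv
#' @param table matrix to write.
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample = rownames(table), table, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write survival tables as CSV
#'
#' Columns `sample`, `time`, `event` and optionally `endpoint`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "time", "event")
  if (!all(req %in% names(df))) {
    stop_("survival CSV needs columns sample, time, event")
  }
  df
}

#' @rdname read_survival_csv
#' @param survival data frame to write.
#' @export
write_survival_csv <- function(survival, path) {
  utils::write.csv(survival, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits the same plain-text formats the analysis functions read:
#' expression TSV, per-sample tumor/normal clone TSVs, a mutation summary
#' CSV, an abundance TSV, a survival CSV, a clinical CSV and the
#' ground-truth CSVs.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop_("`cohort` must come from generate_cohort()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_abundance_tsv(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_survival_csv(cohort$survival, file.path(dir, "survival.csv"))
  utils::write.csv(cohort$mutation, file.path(dir, "mutation.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth$samples, file.path(dir, "truth_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth$taxa, file.path(dir, "truth_taxa.csv"),
                   row.names = FALSE, quote = FALSE)
  tcr_dir <- file.path(dir, "tcr")
  dir.create(tcr_dir, showWarnings = FALSE)
  for (sid in names(cohort$repertoires)) {
    pair <- cohort$repertoires[[sid]]
    write_clone_tsv(pair$tumor, file.path(tcr_dir, paste0(sid, "_tumor.tsv")))
    write_clone_tsv(pair$normal, file.path(tcr_dir, paste0(sid, "_normal.tsv")))
  }
  invisible(dir)
}

#' Read a cohort configuration from a YAML key/value file
#'
#' Keys mirror the arguments of [cohort_config()]; absent keys fall back
#' to the defaults.
#'
#' @param path YAML file path.
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop_(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  do.call(cohort_config, vals)
}
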