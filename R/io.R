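#' Map GENCODE biotypes to RNA classes
#'
#' The lncRNA class covers both the current umbrella biotype `lncRNA` and the
#' older subtype vocabulary (`antisense`, `lincRNA`, `processed_transcript`,
#' `sense_intronic`, `sense_overlapping`, `TEC`); `protein_coding` maps to
#' mRNA, `miRNA` to miRNA, everything else to `other`.
#'
#' @param biotype Character vector of GENCODE biotypes.
#' @return Character vector in `{mRNA, lncRNA, miRNA, other}`.
#' @export
biotype_to_class <- function(biotype) {
  lnc <- c("antisense", "lincRNA", "lncRNA", "processed_transcript",
           "sense_intronic", "sense_overlapping", "TEC")
  out <- rep("other", length(biotype))
  out[biotype %in% lnc] <- "lncRNA"
  out[biotype == "protein_coding"] <- "mRNA"
  out[biotype == "miRNA"] <- "miRNA"
  out
}

#' Read gene biotypes from a GTF file and classify them
#'
#' Parses gene feature lines, extracting the `gene_id` and `gene_type`
#' attributes (`gene_biotype` accepted as a fallback key). Coordinates are
#' parsed but unused; only the attributes matter here.
#'
#' @param gtf_path Path to a GTF file.
#' @return A `gene_annotation` data.frame with columns `gene_id`, `biotype`,
#'   `rna_class`.
#' @export
classify_biotypes <- function(gtf_path) {
  lines <- readLines(gtf_path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) stopf("GTF '%s' has no feature lines", gtf_path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stopf("GTF parse error at line %d: expected 9 tab-separated fields",
          idx[which(nf < 9)[1]])
  feature <- vapply(fields, `[[`, character(1), 3)
  gene_rows <- which(feature == "gene")
  if (length(gene_rows) == 0)
    stopf("GTF '%s' contains no gene feature lines", gtf_path)
  attr_str <- vapply(fields[gene_rows], `[[`, character(1), 9)
  get_attr <- function(str, key) {
    m <- regmatches(str, regexec(paste0(key, ' "([^"]*)"'), str))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  gene_id <- vapply(attr_str, get_attr, character(1), "gene_id",
                    USE.NAMES = FALSE)
  biotype <- vapply(attr_str, get_attr, character(1), "gene_type",
                    USE.NAMES = FALSE)
  fb <- is.na(biotype)
  biotype[fb] <- vapply(attr_str[fb], get_attr, character(1), "gene_biotype",
                        USE.NAMES = FALSE)
  if (anyNA(gene_id))
    stopf("GTF parse error at line %d: missing gene_id attribute",
          idx[gene_rows[which(is.na(gene_id))[1]]])
  if (anyNA(biotype))
    stopf("GTF parse error at line %d: missing gene_type/gene_biotype attribute",
          idx[gene_rows[which(is.na(biotype))[1]]])
  if (anyDuplicated(gene_id))
    stopf("duplicate gene_id '%s' in GTF", gene_id[duplicated(gene_id)][1])
  ann <- data.frame(gene_id = gene_id, biotype = biotype,
                    rna_class = biotype_to_class(biotype),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read an expression TSV (column 1 = gene id, header = sample ids)
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stopf("expression file '%s' is empty or has no sample columns", path)
  gene_ids <- dt[[1]]
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene id '%s' in '%s'",
          gene_ids[duplicated(gene_ids)][1], path)
  body <- dt[, -1, drop = FALSE]
  notnum <- !vapply(body, is.numeric, logical(1))
  if (any(notnum))
    stopf("non-numeric expression values in column '%s' of '%s'",
          names(body)[notnum][1], path)
  mat <- as.matrix(body)
  rownames(mat) <- gene_ids
  check_expression_matrix(mat, sprintf("expression file '%s'", path))
}

#' Load expression into per-class matrices
#'
#' Reads one or more expression TSVs, stacks them, routes every gene to its
#' RNA-class matrix according to the annotation, and drops `other`-class and
#' unannotated genes with a message. Sample order must agree across files and
#' is preserved identically in the three matrices.
#'
#' @param paths Character vector of expression TSV paths.
#' @param annotation A [classify_biotypes()] result (or any data.frame with
#'   `gene_id` and `rna_class`).
#' @return An `expression_bundle`: list of matrices `mrna`, `lncrna`, `mirna`.
#' @export
load_expression <- function(paths, annotation) {
  mats <- lapply(paths, read_expression_tsv)
  samp <- colnames(mats[[1]])
  for (m in mats)
    if (!identical(colnames(m), samp))
      stopf("expression files disagree on sample ids or order")
  mat <- do.call(rbind, mats)
  if (anyDuplicated(rownames(mat)))
    stopf("duplicate gene id '%s' across expression files",
          rownames(mat)[duplicated(rownames(mat))][1])
  cls <- annotation$rna_class[match(rownames(mat), annotation$gene_id)]
  cls[is.na(cls)] <- "other"
  dropped <- sum(cls == "other")
  if (dropped > 0)
    message(sprintf("dropping %d gene(s) outside the mRNA/lncRNA/miRNA classes",
                    dropped))
  bundle <- list(mrna = mat[cls == "mRNA", , drop = FALSE],
                 lncrna = mat[cls == "lncRNA", , drop = FALSE],
                 mirna = mat[cls == "miRNA", , drop = FALSE])
  structure(bundle, class = "expression_bundle")
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (name, description, then members).
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("GMT '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stopf("malformed GMT line %d: fewer than 3 fields", bad[1])
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name '%s' in GMT", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  attr(sets, "description") <- setNames(
    vapply(fields, `[[`, character(1), 2), nm)
  sets
}

#' Read a miRNA-target interaction catalog TSV
#'
#' Expected header: `mirna_id  target_id  target_class  ago_sites`.
#'
#' @param path Path to the TSV.
#' @return An `interaction_catalog` data.frame.
#' @export
read_interactions <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("mirna_id", "target_id", "target_class", "ago_sites")
  if (!all(need %in% names(dt)))
    stopf("interaction table must have columns: %s", paste(need, collapse = ", "))
  dt <- dt[, need]
  if (!is.numeric(dt$ago_sites) || any(is.na(dt$ago_sites)) ||
      any(dt$ago_sites < 0) || any(dt$ago_sites != round(dt$ago_sites)))
    stopf("ago_sites must be non-negative integers")
  dt$ago_sites <- as.integer(dt$ago_sites)
  if (!all(dt$target_class %in% c("mRNA", "lncRNA")))
    stopf("unknown target_class '%s'",
          setdiff(dt$target_class, c("mRNA", "lncRNA"))[1])
  key <- paste(dt$mirna_id, dt$target_id)
  if (anyDuplicated(key))
    stopf("duplicate interaction pair '%s'", key[duplicated(key)][1])
  class(dt) <- c("interaction_catalog", "data.frame")
  dt
}

#' Read a sample metadata TSV
#'
#' Expected header: `sample_id  condition  survival_days  event`. Condition is
#' normalized case-insensitively to `tumor`/`normal`. Missing survival fields
#' are tolerated here and enforced only when survival analysis is run.
#'
#' @param path Path to the TSV.
#' @return A `sample_table` data.frame.
#' @export
read_samples <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  need <- c("sample_id", "condition", "survival_days", "event")
  if (!all(need %in% names(dt)))
    stopf("sample table must have columns: %s", paste(need, collapse = ", "))
  dt <- dt[, need]
  dt$sample_id <- as.character(dt$sample_id)
  if (anyDuplicated(dt$sample_id))
    stopf("duplicate sample id '%s'", dt$sample_id[duplicated(dt$sample_id)][1])
  cond <- tolower(as.character(dt$condition))
  if (any(is.na(cond)) || !all(cond %in% c("tumor", "normal")))
    stopf("unknown condition label '%s' (expected tumor/normal)",
          setdiff(unique(dt$condition), c("tumor", "normal", "Tumor", "Normal",
                                          "TUMOR", "NORMAL"))[1] %||% "NA")
  dt$condition <- cond
  if (any(dt$survival_days < 0, na.rm = TRUE))
    stopf("negative survival_days")
  if (!all(dt$event %in% c(0L, 1L, NA)))
    stopf("event must be 0, 1 or missing")
  class(dt) <- c("sample_table", "data.frame")
  dt
}

# ---- writers (round-trip counterparts of the readers) -----------------------

#' Write an expression matrix as TSV with full double precision
#' @param mat Genes x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  check_expression_matrix(mat)
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- chr[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a gene annotation as a gene-line GTF
#' @param annotation Data.frame with `gene_id` and `biotype`.
#' @param path Output path.
#' @export
write_gene_gtf <- function(annotation, path) {
  n <- nrow(annotation)
  start <- seq_len(n) * 10000L
  lines <- sprintf(
    'chr1\tsim\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "%s";',
    start, start + 999L, annotation$gene_id, annotation$biotype)
  writeLines(c("## synthetic gene annotation", lines), path)
  invisible(path)
}

#' Write a sample table TSV
#' @param samples Sample table data.frame.
#' @param path Output path.
#' @export
write_samples_tsv <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an interaction catalog TSV
#' @param interactions Interaction data.frame.
#' @param path Output path.
#' @export
write_interactions_tsv <- function(interactions, path) {
  data.table::fwrite(interactions, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    setNames(rep("synthetic gene set", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
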