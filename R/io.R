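#' Read quantification tables from TSV files
#'
#' Reads the long-format peptide table (`peptide_id`, `sample_id`,
#' `intensity`, `taxa`), the long-format protein-group table (`group_id`,
#' `sample_id`, `intensity`), the sample design, and optionally the lineage
#' database and annotation map. Intensities must be non-negative (violations
#' are reported with their row number); absent cells are missing
#' observations, never zeros. Every design sample must appear in at least
#' one quantification table.
#'
#' @param peptides,proteins,design Paths to TSV files.
#' @param lineages,annotations Optional paths to TSV files.
#' @return List shaped like the output of [simulate_quant_tables()].
#' @export
read_quant_tables <- function(peptides, proteins, design,
                              lineages = NULL, annotations = NULL) {
  read_tsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  pep <- read_tsv(peptides)
  require_columns(pep, c("peptide_id", "sample_id", "intensity"),
                  sprintf("peptide table '%s'", peptides))
  check_intensity(pep, peptides)
  prot <- read_tsv(proteins)
  require_columns(prot, c("group_id", "sample_id", "intensity"),
                  sprintf("protein table '%s'", proteins))
  check_intensity(prot, proteins)
  des <- validate_design(read_tsv(design))
  known <- unique(c(pep$sample_id, prot$sample_id))
  orphans <- setdiff(des$sample_id, known)
  if (length(orphans) > 0L) {
    stop(sprintf("design sample(s) absent from quantification tables: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  lin <- NULL
  if (!is.null(lineages)) {
    lin <- read_tsv(lineages)
    require_columns(lin, c("taxon_id", tax_ranks()),
                    sprintf("lineage table '%s'", lineages))
    if (anyDuplicated(lin$taxon_id)) {
      stop("duplicate taxon ids in lineage table", call. = FALSE)
    }
    for (r in tax_ranks()) lin[[r]][!nzchar(trimws(lin[[r]]))] <- NA
  }
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- read_tsv(annotations)
    require_columns(ann, "group_id",
                    sprintf("annotation table '%s'", annotations))
    if (anyDuplicated(ann$group_id)) {
      stop("duplicate group ids in annotation table", call. = FALSE)
    }
  }
  structure(list(peptides = pep, proteins = prot, annotations = ann,
                 lineages = lin, design = des),
            class = "mp_quant")
}

check_intensity <- function(df, path) {
  if (!is.numeric(df$intensity)) {
    stop(sprintf("'%s': intensity column is not numeric", path),
         call. = FALSE)
  }
  bad <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': negative or missing intensity at row %d", path,
                 bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' Write quantification tables as TSV files
#'
#' Writes the peptide and protein-group long tables, the design, and (when
#' present) the lineage database and annotation map into a directory;
#' [read_quant_tables()] round-trips the output losslessly.
#'
#' @param quant An `mp_quant` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_quant_tables <- function(quant, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(quant$peptides, "peptides")
  wr(quant$proteins, "proteins")
  wr(quant$design, "design")
  if (!is.null(quant$lineages)) wr(quant$lineages, "lineages")
  if (!is.null(quant$annotations)) wr(quant$annotations, "annotations")
  invisible(unlist(paths))
}

write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
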