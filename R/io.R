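# Shared readers/writers: FASTA, taxonomy tables, provenance JSON.

#' Read a FASTA file into a named DNAStringSet
#'
#' Tolerates CRLF line endings; rejects duplicate record ids. The record id
#' is the header up to the first whitespace.
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA ids in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  seqs
}

#' Write sequences as FASTA (80-column wrap, LF endings)
#'
#' @param seqs Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_dna_set(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write a taxonomy table
#'
#' One row per entry: `id<TAB>superkingdom;phylum;class;order;family;genus;
#' species`, missing ranks rendered as `"NA"`. Rank names containing the
#' `";"` field separator are rejected.
#'
#' @param ids Character vector of entry ids.
#' @param lineages data.frame with the 7 rank columns (same row order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(ids, lineages, path) {
  m <- as_lineage_matrix(lineages)
  stopifnot(length(ids) == nrow(m))
  bad <- which(apply(m, 1L, function(r) any(grepl(";", r, fixed = TRUE))))
  if (length(bad)) {
    stop(sprintf("lineage for '%s' contains ';' which is the rank separator",
                 ids[bad[1L]]), call. = FALSE)
  }
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(paste(ids, format_lineage(m), sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a taxonomy table written by [write_taxonomy_table()]
#'
#' @param path Taxonomy-table path.
#' @return data.frame with column `id` plus the 7 rank columns.
#' @export
read_taxonomy_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- cbind(data.frame(id = character(0), stringsAsFactors = FALSE),
                 parse_lineage_string(character(0)))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed taxonomy row %d: expected id<TAB>lineage",
                 bad[1L]), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  lin <- tryCatch(
    parse_lineage_string(vapply(parts, `[[`, character(1L), 2L)),
    error = function(e) stop(sprintf("in %s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), lin)
}

#' Write a provenance record
#'
#' Every pipeline stage writes a JSON record of its parameters, RNG seed,
#' package version and input-file digests so the stage can be re-run
#' exactly.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param params Named list of parameters (serialized verbatim).
#' @param inputs Character vector of input file paths to digest (optional).
#' @param extra Named list merged into the record (optional).
#' @return The record, invisibly.
#' @export
write_provenance <- function(path, stage, params = list(), inputs = character(0),
                             extra = list()) {
  digests <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(existing))
  } else list()
  rec <- c(list(stage = stage,
                package = "ampliref",
                version = as.character(utils::packageVersion("ampliref")),
                params = params,
                input_digests = digests),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(rec)
}
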