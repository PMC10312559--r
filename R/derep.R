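# Dereplication and curation: NA-lineage filtering, identical-sequence
# collapse, rank-wise taxonomy reconciliation, and emission of the final
# FASTA + taxonomy reference database.

#' Filter out entries with uninformative lineages
#'
#' Under the default `"all"` mode an entry is discarded iff all five of
#' phylum, class, order, family and genus are missing — such records are
#' typically environmental samples with no classification value. The
#' discarded entries are returned (and later written to a side file), never
#' silently deleted. The stricter `"any"` mode discards an entry when any
#' of the five ranks is missing.
#'
#' @param entries data.frame carrying the 7 lineage columns.
#' @param na_mode `"all"` (default) or `"any"`.
#' @return list with elements `kept` and `discarded`.
#' @export
filter_na_lineages <- function(entries, na_mode = c("all", "any")) {
  na_mode <- match.arg(na_mode)
  five <- c("phylum", "class", "order", "family", "genus")
  miss <- is.na(as_lineage_matrix(entries[, LINEAGE_RANKS, drop = FALSE])[,
                                  five, drop = FALSE])
  drop <- if (na_mode == "all") rowSums(miss) == length(five) else
    rowSums(miss) > 0L
  list(kept = entries[!drop, , drop = FALSE],
       discarded = entries[drop, , drop = FALSE])
}

#' Collapse identical sequences into representative entries
#'
#' Groups rows by exact (uppercase) sequence identity; each group becomes
#' one entry whose representative id joins the sorted member accessions
#' with `"|"` and whose taxids are the sorted unique member taxids.
#' Reverse-complement duplicates are deliberately not merged.
#'
#' @param entries data.frame with columns `accession` (or
#'   `subject_accession`), `taxids` and `sequence` (or `subject_sequence`),
#'   plus the 7 lineage columns.
#' @return data.frame with one row per distinct sequence: columns
#'   `representative_id`, `accessions` (\"|\"-joined), `taxids`
#'   (";"-joined), `n_members`, `sequence`, plus member lineages as a list
#'   column `member_lineages` for reconciliation.
#' @export
collapse_identical <- function(entries) {
  acc_col <- if ("accession" %in% names(entries)) "accession" else
    "subject_accession"
  seq_col <- if ("sequence" %in% names(entries)) "sequence" else
    "subject_sequence"
  seqs <- toupper(entries[[seq_col]])
  groups <- split(seq_len(nrow(entries)), seqs)
  rows <- lapply(groups, function(ix) {
    accs <- sort(unique(entries[[acc_col]][ix]))
    tx <- unlist(strsplit(entries$taxids[ix], ";", fixed = TRUE))
    tx <- sort(unique(tx[!is.na(tx) & nzchar(tx)]))
    data.frame(representative_id = paste(accs, collapse = "|"),
               accessions = paste(accs, collapse = "|"),
               taxids = if (length(tx)) paste(tx, collapse = ";") else
                 NA_character_,
               n_members = length(ix),
               sequence = toupper(entries[[seq_col]][ix[1L]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$member_lineages <- lapply(groups, function(ix) {
    as_lineage_matrix(entries[ix, LINEAGE_RANKS, drop = FALSE])
  })
  out <- out[order(out$representative_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile the taxonomy of a collapsed entry
#'
#' Rank-wise over the member lineages: missing values are first dropped
#' from multi-valued rank sets (so "Chordata, NA" resolves to "Chordata");
#' a rank still holding more than one distinct name becomes missing (so
#' species "Badis assamensis, Badis badis" resolves to missing while genus
#' "Badis" is retained); finally the strict-LCA shape is enforced so no
#' named rank sits below the first conflicting rank. This is exactly
#' [lowest_common_lineage()] applied to the member lineages.
#'
#' @param member_lineages Matrix/data.frame of member lineages (7 rank
#'   columns).
#' @return Named character(7) reconciled lineage.
#' @export
reconcile_entry_taxonomy <- function(member_lineages) {
  lowest_common_lineage(member_lineages)
}

#' Build the curated reference database
#'
#' Pipeline: [filter_na_lineages()] (discarded entries kept in a side
#' table) -> [collapse_identical()] -> [reconcile_entry_taxonomy()] per
#' entry. When `out_dir` is given, writes `<name>_derep.fasta`,
#' `<name>_taxonomy.txt`, `<name>_discarded_na.fasta`,
#' `<name>_discarded_na.txt` and `provenance.json`. Running the function on
#' its own output reproduces the output byte-for-byte.
#'
#' @param hit_table Expanded hit table (from [expand_seeds()]`$hits`, or a
#'   database re-read with [read_ref_db()]): accession/sequence/taxids
#'   columns plus the 7 lineage columns.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param name Output file prefix (default `"reference"`).
#' @param na_mode NA-filter mode, see [filter_na_lineages()].
#' @return A `ref_database`: list with `entries` (representative_id,
#'   accessions, taxids, n_members, sequence + 7 lineage columns),
#'   `discarded_na`, and `provenance`.
#' @export
build_reference <- function(hit_table, out_dir = NULL, name = "reference",
                            na_mode = c("all", "any")) {
  na_mode <- match.arg(na_mode)
  if (!nrow(hit_table)) {
    entries <- cbind(
      data.frame(representative_id = character(0), accessions = character(0),
                 taxids = character(0), n_members = integer(0),
                 sequence = character(0), stringsAsFactors = FALSE),
      as.data.frame(as_lineage_matrix(empty_lineage())[0, , drop = FALSE],
                    stringsAsFactors = FALSE))
    db <- structure(list(entries = entries, discarded_na = hit_table,
                         provenance = list(na_mode = na_mode)),
                    class = "ref_database")
    if (!is.null(out_dir)) {
      warning("empty hit table: writing an empty reference database")
      write_ref_db(db, out_dir, name)
    }
    return(db)
  }
  split_tab <- filter_na_lineages(hit_table, na_mode)
  collapsed <- collapse_identical(split_tab$kept)
  if (nrow(collapsed)) {
    lin <- do.call(rbind, lapply(collapsed$member_lineages,
                                 reconcile_entry_taxonomy))
    lin <- as.data.frame(lin, stringsAsFactors = FALSE)
    names(lin) <- LINEAGE_RANKS
  } else {
    lin <- as.data.frame(as_lineage_matrix(empty_lineage())[0, , drop = FALSE],
                         stringsAsFactors = FALSE)
  }
  entries <- cbind(collapsed[, c("representative_id", "accessions", "taxids",
                                 "n_members", "sequence")], lin)
  rownames(entries) <- NULL
  db <- structure(list(
    entries = entries,
    discarded_na = split_tab$discarded,
    provenance = list(na_mode = na_mode,
                      input_rows = nrow(hit_table),
                      kept_rows = nrow(split_tab$kept),
                      discarded_rows = nrow(split_tab$discarded),
                      entries = nrow(entries))),
    class = "ref_database")
  if (!is.null(out_dir)) write_ref_db(db, out_dir, name)
  db
}

#' @export
print.ref_database <- function(x, ...) {
  cat(sprintf("ref_database: %d entries (%d discarded by NA-lineage filter)\n",
              nrow(x$entries), nrow(x$discarded_na)))
  invisible(x)
}

#' Write a reference database to disk
#'
#' @param db A `ref_database`.
#' @param out_dir Output directory.
#' @param name File prefix.
#' @return `out_dir`, invisibly.
#' @export
write_ref_db <- function(db, out_dir, name = "reference") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  e <- db$entries
  write_fasta(stats::setNames(e$sequence, e$representative_id),
              file.path(out_dir, paste0(name, "_derep.fasta")))
  write_taxonomy_table(e$representative_id, e[, LINEAGE_RANKS, drop = FALSE],
                       file.path(out_dir, paste0(name, "_taxonomy.txt")))
  d <- db$discarded_na
  acc_col <- if ("accession" %in% names(d)) "accession" else "subject_accession"
  seq_col <- if ("sequence" %in% names(d)) "sequence" else "subject_sequence"
  if (nrow(d)) {
    write_fasta(stats::setNames(toupper(d[[seq_col]]), d[[acc_col]]),
                file.path(out_dir, paste0(name, "_discarded_na.fasta")))
    write_taxonomy_table(d[[acc_col]], d[, LINEAGE_RANKS, drop = FALSE],
                         file.path(out_dir, paste0(name, "_discarded_na.txt")))
  } else {
    file.create(file.path(out_dir, paste0(name, "_discarded_na.fasta")))
    file.create(file.path(out_dir, paste0(name, "_discarded_na.txt")))
  }
  write_provenance(file.path(out_dir, "provenance.json"), "build_reference",
                   params = db$provenance)
  invisible(out_dir)
}

#' Read a reference database back from its FASTA + taxonomy files
#'
#' The result can be fed straight back into [build_reference()] (the
#' pipeline is a fixpoint on its own output) or into [compare_ref_db()].
#'
#' @param fasta_path,taxonomy_path Paths written by [write_ref_db()].
#' @return data.frame with columns `accession`, `taxids`, `sequence` and
#'   the 7 lineage columns, one row per database entry.
#' @export
read_ref_db <- function(fasta_path, taxonomy_path) {
  tax <- read_taxonomy_table(taxonomy_path)
  if (nrow(tax)) {
    seqs <- read_fasta(fasta_path)
    ord <- match(tax$id, names(seqs))
    if (anyNA(ord)) {
      stop("taxonomy ids missing from FASTA: ",
           paste(utils::head(tax$id[is.na(ord)], 5L), collapse = ", "),
           call. = FALSE)
    }
    sequence <- as.character(seqs)[ord]
  } else {
    sequence <- character(0)
  }
  out <- cbind(data.frame(accession = tax$id, taxids = NA_character_,
                          sequence = sequence, stringsAsFactors = FALSE),
               tax[, LINEAGE_RANKS, drop = FALSE])
  rownames(out) <- NULL
  out
}
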