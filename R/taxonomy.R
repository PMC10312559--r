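# Taxonomy store: NCBI taxdump-dialect reader, accession -> taxid maps,
# fixed-rank lineage lookup, and lowest-common-agreed-taxonomy computation.

#' The seven canonical ranks used throughout the package
#' @export
LINEAGE_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' An all-missing lineage
#' @return Named character(7) of `NA`.
#' @keywords internal
empty_lineage <- function() {
  stats::setNames(rep(NA_character_, 7L), LINEAGE_RANKS)
}

parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Load an NCBI taxdump-dialect taxonomy
#'
#' Reads `nodes.dmp` (taxid, parent taxid, rank, ...) and `names.dmp`
#' (taxid, name, unique name, name class), keeping scientific names only.
#' Ranks outside the seven canonical ranks are retained in the parent graph
#' (they are traversed during lineage lookup) but never reported.
#'
#' The legacy rank name `"domain"` is accepted as a synonym of
#' `"superkingdom"`.
#'
#' @param nodes_path,names_path Paths to the two pipe-delimited files.
#' @param acc2taxid Optional path to an accession-to-taxid map (see
#'   [read_acc2taxid()]).
#' @param membership Optional path to a representative-accession membership
#'   map (see [read_membership()]).
#' @return A `taxonomy_store` object.
#' @export
load_taxdump <- function(nodes_path, names_path, acc2taxid = NULL,
                         membership = NULL) {
  nodes <- parse_dmp(nodes_path)
  bad <- which(lengths(nodes) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s: expected at least 3 fields",
                 bad[1L], nodes_path), call. = FALSE)
  }
  taxid <- vapply(nodes, function(x) trimws(x[[1L]]), character(1L))
  parent <- vapply(nodes, function(x) trimws(x[[2L]]), character(1L))
  rank <- vapply(nodes, function(x) trimws(x[[3L]]), character(1L))
  rank[rank == "domain"] <- "superkingdom"
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid in nodes file", call. = FALSE)
  }
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent)) {
    stop(sprintf("nodes file references unknown parent taxid(s): %s",
                 paste(utils::head(missing_parent, 5L), collapse = ", ")),
         call. = FALSE)
  }

  nm <- parse_dmp(names_path)
  bad <- which(lengths(nm) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s: expected at least 2 fields",
                 bad[1L], names_path), call. = FALSE)
  }
  nm_taxid <- vapply(nm, function(x) trimws(x[[1L]]), character(1L))
  nm_name <- vapply(nm, function(x) trimws(x[[2L]]), character(1L))
  nm_class <- vapply(nm, function(x) {
    if (length(x) >= 4L) trimws(x[[4L]]) else "scientific name"
  }, character(1L))
  keep <- nm_class == "scientific name"
  name_of <- stats::setNames(nm_name[keep], nm_taxid[keep])

  store <- structure(list(
    parent = stats::setNames(parent, taxid),
    rank = stats::setNames(rank, taxid),
    name = name_of,
    acc2taxid = character(0),
    membership = data.frame(representative = character(0),
                            member = character(0), taxid = character(0),
                            stringsAsFactors = FALSE)
  ), class = "taxonomy_store")
  if (!is.null(acc2taxid)) store$acc2taxid <- read_acc2taxid(acc2taxid)
  if (!is.null(membership)) store$membership <- read_membership(membership)
  store
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat(sprintf("taxonomy_store: %d taxids, %d mapped accessions, %d membership rows\n",
              length(x$parent), length(x$acc2taxid), nrow(x$membership)))
  invisible(x)
}

#' Read an accession-to-taxid map
#'
#' Accepts the NCBI accession2taxid TSV dialect (4 columns with header:
#' accession, accession.version, taxid, gi) or a simplified 2-column
#' accession<TAB>taxid file. Both the versioned and unversioned accession
#' forms are registered as keys.
#'
#' @param path TSV path.
#' @return Named character vector: accession -> taxid.
#' @export
read_acc2taxid <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) >= 3L) {
    # NCBI dialect carries a header line
    if (tolower(df[1L, 1L]) == "accession") df <- df[-1L, , drop = FALSE]
    acc <- df[[2L]]
    taxid <- df[[3L]]
  } else if (ncol(df) == 2L) {
    if (tolower(df[1L, 1L]) == "accession") df <- df[-1L, , drop = FALSE]
    acc <- df[[1L]]
    taxid <- df[[2L]]
  } else {
    stop(sprintf("accession2taxid file %s: expected 2 or >=3 columns", path),
         call. = FALSE)
  }
  map <- stats::setNames(taxid, acc)
  bare <- strip_version(acc)
  extra <- !(bare %in% names(map))
  c(map, stats::setNames(taxid[extra], bare[extra]))
}

#' Read a representative-accession membership map
#'
#' TSV dialect: `representative_accession<TAB>member_accession<TAB>taxid`.
#' Representative accessions collapse identical sequences from multiple
#' original accessions (possibly multiple taxids).
#'
#' @param path TSV path.
#' @return data.frame with columns `representative`, `member`, `taxid`.
#' @export
read_membership <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(representative = character(0), member = character(0),
                      taxid = character(0), stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 3L) {
    stop(sprintf("membership file %s: expected 3 columns", path), call. = FALSE)
  }
  names(df) <- c("representative", "member", "taxid")
  df
}

#' Strip the version suffix from an accession
#' @param acc Character vector of accession or accession.version strings.
#' @return Accessions without the trailing `.N`.
#' @export
strip_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Map accessions to taxids
#'
#' @param store A `taxonomy_store`.
#' @param accessions Character vector (versioned or not).
#' @return Character vector of taxids, `NA` where unresolvable.
#' @export
accession_taxid <- function(store, accessions) {
  hit <- store$acc2taxid[accessions]
  miss <- is.na(hit)
  if (any(miss)) {
    hit[miss] <- store$acc2taxid[strip_version(accessions[miss])]
  }
  unname(hit)
}

#' Fixed-rank lineage of a taxid
#'
#' Walks parent pointers from `taxid` to the root, recording the scientific
#' name at each of the seven canonical ranks (superkingdom, phylum, class,
#' order, family, genus, species). Ranks not encountered on the path are
#' `NA` (the missing-value sentinel used everywhere in this package).
#'
#' @param store A `taxonomy_store`.
#' @param taxid Taxid (character or numeric scalar).
#' @param permissive If `TRUE`, an unknown taxid yields an all-`NA` lineage
#'   instead of an error.
#' @return Named character(7).
#' @export
get_lineage <- function(store, taxid, permissive = FALSE) {
  taxid <- as.character(taxid)
  if (!taxid %in% names(store$parent)) {
    if (permissive) return(empty_lineage())
    stop(sprintf("unknown taxid '%s'", taxid), call. = FALSE)
  }
  lin <- empty_lineage()
  cur <- taxid
  steps <- 0L
  max_steps <- length(store$parent) + 1L
  repeat {
    r <- store$rank[[cur]]
    if (r %in% LINEAGE_RANKS) {
      nm <- store$name[cur]
      lin[[r]] <- if (is.na(nm)) NA_character_ else unname(nm)
    }
    parent <- store$parent[[cur]]
    if (parent == cur) break  # root points to itself in the taxdump dialect
    cur <- parent
    steps <- steps + 1L
    if (steps > max_steps) {
      stop(sprintf("cycle detected in taxonomy graph while resolving taxid '%s'",
                   taxid), call. = FALSE)
    }
  }
  lin
}

#' Lineages for a vector of taxids
#'
#' @inheritParams get_lineage
#' @param taxids Character/numeric vector.
#' @return data.frame with one row per taxid and the 7 rank columns.
#' @export
get_lineages <- function(store, taxids, permissive = FALSE) {
  if (!length(taxids)) {
    df <- as.data.frame(matrix(character(0), 0L, 7L),
                        stringsAsFactors = FALSE)
    names(df) <- LINEAGE_RANKS
    return(df)
  }
  rows <- lapply(taxids, function(t) {
    if (is.na(t)) empty_lineage() else get_lineage(store, t, permissive)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- LINEAGE_RANKS
  rownames(df) <- NULL
  df
}

#' Lowest common agreed taxonomy across lineages
#'
#' Walks the seven ranks from superkingdom downward. At each rank the
#' distinct non-missing values are collected: if exactly one remains it is
#' kept (missing entries do not veto agreement — "Chordata, NA" resolves to
#' "Chordata"); if none remain the rank stays missing and the walk
#' continues; at the first rank with two or more distinct values, that rank
#' and every lower rank become missing (strict LCA: a shared name below a
#' conflict is treated as a homonym, not agreement).
#'
#' The operation is a semilattice meet: commutative, associative and
#' idempotent.
#'
#' @param lineages A list of named character(7) lineages, or a data.frame /
#'   matrix with the 7 rank columns.
#' @return Named character(7).
#' @export
lowest_common_lineage <- function(lineages) {
  m <- as_lineage_matrix(lineages)
  if (nrow(m) == 0L) stop("empty lineage list", call. = FALSE)
  out <- empty_lineage()
  for (i in seq_along(LINEAGE_RANKS)) {
    vals <- unique(m[, i])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 1L) {
      out[[i]] <- vals
    } else if (length(vals) > 1L) {
      break  # conflict: this rank and all lower ranks stay NA
    }
  }
  out
}

# Coerce list-of-lineages / data.frame / matrix to a character matrix with
# the 7 rank columns.
as_lineage_matrix <- function(lineages) {
  if (is.matrix(lineages)) {
    m <- lineages
  } else if (is.data.frame(lineages)) {
    m <- as.matrix(lineages[, LINEAGE_RANKS, drop = FALSE])
  } else if (is.list(lineages)) {
    if (!length(lineages)) stop("empty lineage list", call. = FALSE)
    m <- do.call(rbind, lapply(lineages, function(l) l[LINEAGE_RANKS]))
  } else if (is.character(lineages) && length(lineages) == 7L) {
    m <- matrix(lineages, nrow = 1L)
  } else {
    stop("cannot interpret input as lineages", call. = FALSE)
  }
  colnames(m) <- LINEAGE_RANKS
  mode(m) <- "character"
  m
}

#' Render a lineage as the semicolon-joined taxonomy-file string
#' @param lineage Named character(7) (or a 7-column data.frame row).
#' @return `"superkingdom;phylum;...;species"` with missing ranks as "NA".
#' @export
format_lineage <- function(lineage) {
  m <- as_lineage_matrix(lineage)
  apply(m, 1L, function(r) paste(ifelse(is.na(r), "NA", r), collapse = ";"))
}

#' Parse semicolon-joined taxonomy strings back into rank columns
#' @param x Character vector of 7-field semicolon-joined lineages.
#' @return data.frame with the 7 rank columns; "NA" fields become `NA`.
#' @export
parse_lineage_string <- function(x) {
  if (!length(x)) {
    df <- as.data.frame(matrix(character(0), 0L, 7L),
                        stringsAsFactors = FALSE)
    names(df) <- LINEAGE_RANKS
    return(df)
  }
  parts <- strsplit(x, ";", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad)) {
    stop(sprintf("lineage row %d has %d fields, expected 7",
                 bad[1L], lengths(parts)[bad[1L]]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  m[m == "NA" | m == ""] <- NA_character_
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- LINEAGE_RANKS
  df
}
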