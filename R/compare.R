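# Overlap and uniqueness between two reference databases: venn-style
# shared/unique counts on accessions and species, and a krona-style table
# of lineage paths unique to each database.

explode_accessions <- function(ids) {
  unique(unlist(strsplit(ids, "|", fixed = TRUE), use.names = FALSE))
}

db_species <- function(tax) {
  sp <- tax$species
  unique(sp[!is.na(sp)])
}

#' Compare two reference databases
#'
#' Accession overlap is computed on individual accessions (representative
#' entries are exploded into their `"|"`-joined members). Species overlap
#' uses the reconciled species binomial, skipping missing species. The
#' unique-taxa table lists, per rank, every cumulative lineage path present
#' in exactly one of the two databases, with the number of entries under
#' it (a krona-style hierarchy as counts).
#'
#' @param db_a,db_b Either `ref_database` objects, data.frames in the
#'   [read_ref_db()] layout, or paths to taxonomy files (format of
#'   [write_taxonomy_table()]).
#' @param names Length-2 labels for the two databases.
#' @return A `db_comparison` list: `summary` (data.frame of totals, shared
#'   and unique counts for accessions and species), `venn` (the same as a
#'   long table), and `unique_taxa` (data.frame `database`, `rank`,
#'   `lineage_path`, `n_entries`).
#' @export
compare_ref_db <- function(db_a, db_b, names = c("db_a", "db_b")) {
  a <- as_comparison_table(db_a)
  b <- as_comparison_table(db_b)

  acc_a <- explode_accessions(a$id)
  acc_b <- explode_accessions(b$id)
  sp_a <- db_species(a)
  sp_b <- db_species(b)

  venn_counts <- function(xa, xb) {
    shared <- length(intersect(xa, xb))
    c(total_a = length(xa), total_b = length(xb), shared = shared,
      unique_a = length(xa) - shared, unique_b = length(xb) - shared,
      union = length(union(xa, xb)))
  }
  acc <- venn_counts(acc_a, acc_b)
  sp <- venn_counts(sp_a, sp_b)
  stopifnot(acc[["union"]] == acc[["total_a"]] + acc[["total_b"]] - acc[["shared"]],
            sp[["union"]] == sp[["total_a"]] + sp[["total_b"]] - sp[["shared"]])

  summary <- data.frame(
    axis = rep(c("accessions", "species"), each = 6L),
    statistic = rep(c(paste0("total_", names[1L]), paste0("total_", names[2L]),
                      "shared", paste0("unique_", names[1L]),
                      paste0("unique_", names[2L]), "union"), 2L),
    count = c(unname(acc), unname(sp)),
    stringsAsFactors = FALSE)

  unique_taxa <- rbind(
    unique_taxa_table(a, b, names[1L]),
    unique_taxa_table(b, a, names[2L]))

  structure(list(summary = summary,
                 venn = summary,
                 unique_taxa = unique_taxa,
                 names = names),
            class = "db_comparison")
}

# Cumulative lineage paths (rank by rank) present in `x` but absent from
# `y`, with entry counts under each path.
unique_taxa_table <- function(x, y, label) {
  paths_of <- function(tax, depth) {
    m <- as_lineage_matrix(tax[, LINEAGE_RANKS, drop = FALSE])
    sub <- m[, seq_len(depth), drop = FALSE]
    named <- !is.na(sub[, depth])
    apply(sub[named, , drop = FALSE], 1L, function(r) {
      paste(ifelse(is.na(r), "NA", r), collapse = ";")
    })
  }
  rows <- list()
  for (d in seq_along(LINEAGE_RANKS)) {
    px <- paths_of(x, d)
    py <- paths_of(y, d)
    uniq <- setdiff(unique(px), unique(py))
    if (!length(uniq)) next
    cnt <- table(px)[uniq]
    rows[[d]] <- data.frame(database = label, rank = LINEAGE_RANKS[d],
                            lineage_path = uniq,
                            n_entries = as.integer(cnt),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(database = character(0), rank = character(0),
                      lineage_path = character(0), n_entries = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_comparison_table <- function(db) {
  if (inherits(db, "ref_database")) {
    tab <- db$entries
    tab$id <- tab$representative_id
    return(tab[, c("id", LINEAGE_RANKS)])
  }
  if (is.character(db) && length(db) == 1L) {
    return(read_taxonomy_table(db))
  }
  if (is.data.frame(db)) {
    if (!"id" %in% names(db)) {
      id_col <- intersect(c("accession", "representative_id"), names(db))
      if (!length(id_col)) stop("comparison table needs an id column",
                                call. = FALSE)
      db$id <- db[[id_col[1L]]]
    }
    missing <- setdiff(LINEAGE_RANKS, names(db))
    if (length(missing)) {
      stop("comparison table lacks rank column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(db[, c("id", LINEAGE_RANKS)])
  }
  stop("cannot interpret database input for comparison", call. = FALSE)
}

#' @export
print.db_comparison <- function(x, ...) {
  cat(sprintf("db_comparison: %s vs %s\n", x$names[1L], x$names[2L]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a database comparison report
#'
#' Emits `report.json`, `summary.tsv`, `venn_counts.tsv` and
#' `unique_taxa_hierarchy.tsv` under `out_dir`.
#'
#' @param comparison A `db_comparison` from [compare_ref_db()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_comparison <- function(comparison, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(comparison$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$venn, file.path(out_dir, "venn_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$unique_taxa,
                     file.path(out_dir, "unique_taxa_hierarchy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(databases = comparison$names,
         summary = comparison$summary,
         unique_taxa = comparison$unique_taxa),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
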