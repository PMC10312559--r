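# Synthetic-corpus generator with recorded ground truth for every pipeline
# stage: taxonomy tree, template sequences, planted primer sites, decoys,
# duplicates and uninformative-lineage entries.
#
# Accessions of one genus are derived from a shared genus template with a
# small point-mutation divergence outside the primer footprints, so
# within-genus sequences form a tight similarity cluster while sequences
# from different genera share nothing but chance identity. This emulates
# the cluster structure of real barcode loci (congeneric sequences are
# mutually alignable, distant taxa are not) and makes iterative expansion
# results independent of sampling order.

#' Specification for a synthetic fixture corpus
#'
#' @param n_genera,species_per_genus,accessions_per_species Tree shape; the
#'   base corpus holds `n_genera * species_per_genus *
#'   accessions_per_species` accessions, two genera per family.
#' @param template_length Length-2 range (bp) of the full template
#'   sequences.
#' @param planted_amplicon_length Length-2 range (bp) of planted product
#'   lengths, primer-to-primer inclusive.
#' @param primers A [primer_set()]; degenerate bases allowed (every
#'   enumerated variant must be searchable, so keep total variants small).
#' @param mismatch_profile Named numeric vector of probabilities over
#'   per-primer mismatch counts `0..k` (names "0","1",...).
#' @param decoy_fraction Fraction of base accessions converted to labeled
#'   decoys (cycling through wrong_orientation, single_primer,
#'   out_of_bounds_length).
#' @param duplicate_fraction Extra accessions added as byte-identical
#'   copies of planted sequences, alternating between the same species and
#'   a congeneric sister species.
#' @param na_lineage_fraction Extra accessions attached to uninformative
#'   taxa (phylum..genus all missing), with sequences derived from a genus
#'   cluster so similarity search still recovers them.
#' @param minus_strand_fraction Fraction of planted accessions stored
#'   reverse-complemented (the forward primer then sits on the minus
#'   strand).
#' @param within_cluster_divergence Per-base point-mutation rate applied
#'   outside primer footprints to each accession of a genus cluster.
#' @param representative_fraction Fraction of planted accessions declared
#'   representative accessions whose membership map lists a second,
#'   congeneric member taxid.
#' @param rng_seed Seed for all generation randomness.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genera = 5L, species_per_genus = 2L,
                         accessions_per_species = 2L,
                         template_length = c(400L, 600L),
                         planted_amplicon_length = c(120L, 180L),
                         primers = primer_set("ACGTTCGAWCTGCAGGTCAT",
                                              "TGCATCGRAGTCCTAGGACT",
                                              name = "synthetic"),
                         mismatch_profile = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
                         decoy_fraction = 0, duplicate_fraction = 0,
                         na_lineage_fraction = 0,
                         minus_strand_fraction = 0.25,
                         within_cluster_divergence = 0.02,
                         representative_fraction = 0,
                         rng_seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            accessions_per_species >= 1L,
            length(template_length) == 2L, length(planted_amplicon_length) == 2L,
            inherits(primers, "primer_set"),
            abs(sum(mismatch_profile) - 1) < 1e-8,
            decoy_fraction >= 0, decoy_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            na_lineage_fraction >= 0, na_lineage_fraction <= 1,
            minus_strand_fraction >= 0, minus_strand_fraction <= 1,
            within_cluster_divergence >= 0, within_cluster_divergence < 0.2)
  if (length(primers$forward) != 1L || length(primers$reverse) != 1L) {
    stop("the fixture generator plants exactly one forward and one reverse primer",
         call. = FALSE)
  }
  flen <- nchar(primers$forward[1L]); rlen <- nchar(primers$reverse[1L])
  if (planted_amplicon_length[1L] <= flen + rlen) {
    stop("planted_amplicon_length must exceed the combined primer lengths",
         call. = FALSE)
  }
  if (template_length[1L] < planted_amplicon_length[2L] + 20L) {
    stop("templates must be at least 20 bp longer than the longest planted amplicon",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Scan one non-degenerate variant over both strands of a sequence;
# footprint coordinates on the plus strand. Internal generator tool (the
# independent test oracle lives in the test helpers).
variant_footprints <- function(variant, seq, max_mm) {
  schars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  k <- nchar(variant)
  n <- length(schars)
  scan_one <- function(pat) {
    pchars <- strsplit(pat, "", fixed = TRUE)[[1L]]
    noff <- n - k + 1L
    if (noff < 1L) return(data.frame(start = integer(0), mism = integer(0)))
    idx <- outer(0:(k - 1L), seq_len(noff), `+`)
    ok <- matrix(iupac_match_table[cbind(rep(pchars, noff), schars[idx])],
                 nrow = k)
    mism <- colSums(!ok)
    sel <- which(mism <= max_mm)
    data.frame(start = sel, mism = as.integer(mism[sel]))
  }
  plus <- scan_one(variant)
  minus <- scan_one(reverse_complement(variant))
  rbind(
    if (nrow(plus)) data.frame(start = plus$start, end = plus$start + k - 1L,
                               strand = "plus", mismatches = plus$mism,
                               stringsAsFactors = FALSE),
    if (nrow(minus)) data.frame(start = minus$start, end = minus$start + k - 1L,
                                strand = "minus", mismatches = minus$mism,
                                stringsAsFactors = FALSE))
}

# All footprints of any variant of one role, with the per-footprint minimum
# mismatch count across variants.
role_footprints <- function(variants, seq, max_mm) {
  hits <- do.call(rbind, lapply(variants, variant_footprints,
                                seq = seq, max_mm = max_mm))
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(hits$start, hits$end, hits$strand)
  best <- tapply(hits$mismatches, key, min)
  first <- hits[!duplicated(key), , drop = FALSE]
  first$mismatches <- as.integer(best[paste(first$start, first$end,
                                            first$strand)])
  first[order(first$start, first$strand), , drop = FALSE]
}

# Mutate a base to one the primer position does not accept (creates a
# guaranteed mismatch against every enumerated variant of that position's
# code), or to a random different base when `against` is NA.
mutate_base <- function(base, against = NA_character_) {
  pool <- if (is.na(against)) setdiff(c("A", "C", "G", "T"), base) else
    setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[against]])
  if (!length(pool)) return(base)  # primer N: cannot force a mismatch
  sample(pool, 1L)
}

#' Generate a synthetic corpus with recorded ground truth
#'
#' Writes, under `out_dir`: `corpus.fasta`, `acc2taxid.tsv` (NCBI 4-column
#' dialect), `nodes.dmp` / `names.dmp` (taxdump dialect), `membership.tsv`
#' and `truth.json`. Every planted primer site is re-scanned before
#' writing; generation fails loudly if the realized footprints or mismatch
#' counts disagree with the recorded truth (e.g. a chance primer match in
#' background sequence), so the emitted truth is self-verified.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created).
#' @return A `fixture_truth` list: `accessions` (per-accession truth
#'   data.frame), `lineages` (ground-truth 7-rank lineages per accession),
#'   `seed_params` (the search parameters the fixture was built for),
#'   `paths` (output files), `spec`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$rng_seed, generate_fixture_impl(spec, out_dir))
}

generate_fixture_impl <- function(spec, out_dir) {
  fwd_variants <- unlist(lapply(spec$primers$forward, expand_degenerate))
  rev_variants <- unlist(lapply(spec$primers$reverse, expand_degenerate))
  if (length(fwd_variants) > 64L || length(rev_variants) > 64L) {
    stop("fixture primers expand to too many variants (> 64)", call. = FALSE)
  }
  flen <- nchar(spec$primers$forward[1L])
  rlen <- nchar(spec$primers$reverse[1L])
  max_mm <- max(as.integer(names(spec$mismatch_profile)))
  mm_levels <- as.integer(names(spec$mismatch_profile))

  # ---- taxonomy tree --------------------------------------------------
  G <- spec$n_genera; S <- spec$species_per_genus; A <- spec$accessions_per_species
  n_families <- ceiling(G / 2L)
  tax <- list(data.frame(taxid = "1", parent = "1", rank = "no rank",
                         name = "root", stringsAsFactors = FALSE),
              data.frame(taxid = "2", parent = "1", rank = "superkingdom",
                         name = "Eukaryota", stringsAsFactors = FALSE),
              data.frame(taxid = "3", parent = "2", rank = "phylum",
                         name = "Chordata", stringsAsFactors = FALSE),
              data.frame(taxid = "4", parent = "3", rank = "class",
                         name = "Actinopteri", stringsAsFactors = FALSE),
              data.frame(taxid = "5", parent = "4", rank = "order",
                         name = "Synthoformes", stringsAsFactors = FALSE))
  next_id <- 10L
  fam_ids <- character(n_families)
  for (f in seq_len(n_families)) {
    fam_ids[f] <- as.character(next_id); next_id <- next_id + 1L
    tax <- c(tax, list(data.frame(
      taxid = fam_ids[f], parent = "5", rank = "family",
      name = sprintf("Synthidae_%02d", f), stringsAsFactors = FALSE)))
  }
  genus_ids <- character(G); genus_names <- character(G)
  species_ids <- matrix("", G, S); species_names <- matrix("", G, S)
  for (g in seq_len(G)) {
    genus_ids[g] <- as.character(next_id); next_id <- next_id + 1L
    genus_names[g] <- sprintf("Synthogenus%02d", g)
    tax <- c(tax, list(data.frame(
      taxid = genus_ids[g], parent = fam_ids[ceiling(g / 2L)], rank = "genus",
      name = genus_names[g], stringsAsFactors = FALSE)))
    for (s in seq_len(S)) {
      species_ids[g, s] <- as.character(next_id); next_id <- next_id + 1L
      species_names[g, s] <- sprintf("%s specimen%02d", genus_names[g], s)
      tax <- c(tax, list(data.frame(
        taxid = species_ids[g, s], parent = genus_ids[g], rank = "species",
        name = species_names[g, s], stringsAsFactors = FALSE)))
    }
  }

  # ---- helpers ---------------------------------------------------------
  all_fwd <- fwd_variants; all_rev <- rev_variants
  with_role <- function(fp, role) {
    fp$role <- rep(role, nrow(fp))
    fp
  }
  check_footprints <- function(seq, expected) {
    got <- rbind(with_role(role_footprints(all_fwd, seq, max_mm), "forward"),
                 with_role(role_footprints(all_rev, seq, max_mm), "reverse"))
    got <- got[order(got$start, got$role), , drop = FALSE]
    expected <- expected[order(expected$start, expected$role), , drop = FALSE]
    isTRUE(all.equal(got[, c("start", "end", "strand", "mismatches", "role")],
                     expected[, c("start", "end", "strand", "mismatches", "role")],
                     check.attributes = FALSE))
  }
  no_footprints <- data.frame(start = integer(0), end = integer(0),
                              strand = character(0), mismatches = integer(0),
                              role = character(0), stringsAsFactors = FALSE)

  # ---- genus templates (self-verified: no stray primer match allowed) --
  templates <- vector("list", G)
  for (g in seq_len(G)) {
    for (try in 1:50) {
      tlen <- sample(spec$template_length[1L]:spec$template_length[2L], 1L)
      plen <- sample(spec$planted_amplicon_length[1L]:spec$planted_amplicon_length[2L], 1L)
      v_f <- sample(fwd_variants, 1L)
      v_r <- sample(rev_variants, 1L)
      core <- paste0(v_f, random_dna(plen - flen - rlen),
                     reverse_complement(v_r))
      start <- sample(10L:(tlen - plen - 9L), 1L)
      background <- random_dna(tlen)
      seq <- paste0(substr(background, 1L, start - 1L), core,
                    substr(background, start + plen, tlen))
      exp <- data.frame(start = c(start, start + plen - rlen),
                        end = c(start + flen - 1L, start + plen - 1L),
                        strand = c("plus", "minus"), mismatches = c(0L, 0L),
                        role = c("forward", "reverse"),
                        stringsAsFactors = FALSE)
      if (check_footprints(seq, exp)) {
        templates[[g]] <- list(seq = seq, start = start,
                               end = start + plen - 1L, plen = plen,
                               v_f = v_f, v_r = v_r)
        break
      }
    }
    if (is.null(templates[[g]])) {
      stop("could not generate a collision-free genus template", call. = FALSE)
    }
  }

  # ---- accession plan --------------------------------------------------
  n_base <- G * S * A
  plan <- data.frame(genus = rep(seq_len(G), each = S * A),
                     species = rep(rep(seq_len(S), each = A), G),
                     kind = "planted", stringsAsFactors = FALSE)
  n_decoy <- round(spec$decoy_fraction * n_base)
  if (n_decoy > 0L) {
    decoy_idx <- unique(round(seq(2L, n_base, length.out = n_decoy)))
    kinds <- c("wrong_orientation", "single_primer", "out_of_bounds_length")
    plan$kind[decoy_idx] <- kinds[(seq_along(decoy_idx) - 1L) %% 3L + 1L]
  }
  n_dup <- round(spec$duplicate_fraction * n_base)
  n_na <- round(spec$na_lineage_fraction * n_base)

  build_planted <- function(g) {
    tpl <- templates[[g]]
    chars <- strsplit(tpl$seq, "", fixed = TRUE)[[1L]]
    fwd_site <- tpl$start:(tpl$start + flen - 1L)
    rev_site <- (tpl$end - rlen + 1L):tpl$end
    protected <- c(fwd_site, rev_site)
    # cluster divergence outside primer footprints
    free <- setdiff(seq_along(chars), protected)
    n_mut <- stats::rbinom(1L, length(free), spec$within_cluster_divergence)
    if (n_mut > 0L) {
      at <- sample(free, n_mut)
      chars[at] <- vapply(chars[at], mutate_base, character(1L))
    }
    # planted primer-site mismatches (forced against every variant)
    m_f <- sample(mm_levels, 1L, prob = spec$mismatch_profile)
    m_r <- sample(mm_levels, 1L, prob = spec$mismatch_profile)
    pchars_f <- strsplit(spec$primers$forward[1L], "", fixed = TRUE)[[1L]]
    pchars_r <- strsplit(reverse_complement(spec$primers$reverse[1L]), "",
                         fixed = TRUE)[[1L]]
    mutable_f <- fwd_site[lengths(IUPAC_SETS[pchars_f]) < 4L]
    mutable_r <- rev_site[lengths(IUPAC_SETS[pchars_r]) < 4L]
    if (m_f > 0L) for (p in sample(mutable_f, m_f)) {
      chars[p] <- mutate_base(chars[p], pchars_f[p - tpl$start + 1L])
    }
    if (m_r > 0L) for (p in sample(mutable_r, m_r)) {
      chars[p] <- mutate_base(chars[p], pchars_r[p - tpl$end + rlen])
    }
    list(seq = paste(chars, collapse = ""), start = tpl$start, end = tpl$end,
         m_f = m_f, m_r = m_r)
  }

  expected_planted <- function(start, end, orientation, m_f, m_r, L) {
    if (orientation == "minus") {
      new_start <- L - end + 1L; new_end <- L - start + 1L
      start <- new_start; end <- new_end
    }
    fs <- if (orientation == "plus") "plus" else "minus"
    rs <- if (orientation == "plus") "minus" else "plus"
    f_span <- if (orientation == "plus") c(start, start + flen - 1L) else
      c(end - flen + 1L, end)
    r_span <- if (orientation == "plus") c(end - rlen + 1L, end) else
      c(start, start + rlen - 1L)
    data.frame(start = c(f_span[1L], r_span[1L]),
               end = c(f_span[2L], r_span[2L]),
               strand = c(fs, rs), mismatches = c(m_f, m_r),
               role = c("forward", "reverse"), stringsAsFactors = FALSE)
  }

  records <- list()
  acc_counter <- 0L
  new_accession <- function() {
    acc_counter <<- acc_counter + 1L
    sprintf("SYN%04d.1", acc_counter)
  }

  for (i in seq_len(nrow(plan))) {
    g <- plan$genus[i]; s <- plan$species[i]; kind <- plan$kind[i]
    acc <- new_accession()
    rec <- NULL
    for (try in 1:25) {
      if (kind == "planted") {
        bp <- build_planted(g)
        orientation <- if (stats::runif(1) < spec$minus_strand_fraction)
          "minus" else "plus"
        seq <- if (orientation == "minus") reverse_complement(bp$seq) else bp$seq
        L <- nchar(seq)
        span <- if (orientation == "minus")
          c(L - bp$end + 1L, L - bp$start + 1L) else c(bp$start, bp$end)
        exp <- expected_planted(bp$start, bp$end, orientation, bp$m_f, bp$m_r,
                                L)
        if (!check_footprints(seq, exp)) next
        rec <- data.frame(
          accession = acc, taxid = species_ids[g, s],
          genus = genus_names[g], species = species_names[g, s],
          kind = "planted", is_decoy = FALSE, decoy_kind = NA_character_,
          has_planted_amplicon = TRUE, amplicon_start = span[1L],
          amplicon_end = span[2L], orientation = orientation,
          product_length = span[2L] - span[1L] + 1L,
          forward_mismatches = bp$m_f, reverse_mismatches = bp$m_r,
          duplicate_group = NA_character_, is_na_lineage = FALSE,
          length = L, sequence = seq, stringsAsFactors = FALSE)
      } else {
        tlen <- sample(spec$template_length[1L]:spec$template_length[2L], 1L)
        v_f <- sample(fwd_variants, 1L); v_r <- sample(rev_variants, 1L)
        if (kind == "out_of_bounds_length") {
          plen <- spec$planted_amplicon_length[2L] + 50L
          tlen <- max(tlen, plen + 40L)
        } else {
          plen <- sample(spec$planted_amplicon_length[1L]:
                           spec$planted_amplicon_length[2L], 1L)
        }
        start <- sample(10L:(tlen - plen - 9L), 1L)
        background <- random_dna(tlen)
        if (kind == "single_primer") {
          seq <- paste0(substr(background, 1L, start - 1L), v_f,
                        substr(background, start + flen, tlen))
          exp <- data.frame(start = start, end = start + flen - 1L,
                            strand = "plus", mismatches = 0L,
                            role = "forward", stringsAsFactors = FALSE)
        } else if (kind == "wrong_orientation") {
          # reverse primer planted un-complemented: both primers face the
          # same direction, no convergent pair exists
          core <- paste0(v_f, random_dna(plen - flen - rlen), v_r)
          seq <- paste0(substr(background, 1L, start - 1L), core,
                        substr(background, start + plen, tlen))
          exp <- data.frame(start = c(start, start + plen - rlen),
                            end = c(start + flen - 1L, start + plen - 1L),
                            strand = c("plus", "plus"),
                            mismatches = c(0L, 0L),
                            role = c("forward", "reverse"),
                            stringsAsFactors = FALSE)
        } else { # out_of_bounds_length: proper orientation, too long
          core <- paste0(v_f, random_dna(plen - flen - rlen),
                         reverse_complement(v_r))
          seq <- paste0(substr(background, 1L, start - 1L), core,
                        substr(background, start + plen, tlen))
          exp <- data.frame(start = c(start, start + plen - rlen),
                            end = c(start + flen - 1L, start + plen - 1L),
                            strand = c("plus", "minus"),
                            mismatches = c(0L, 0L),
                            role = c("forward", "reverse"),
                            stringsAsFactors = FALSE)
        }
        if (!check_footprints(seq, exp)) next
        rec <- data.frame(
          accession = acc, taxid = species_ids[g, s],
          genus = genus_names[g], species = species_names[g, s],
          kind = kind, is_decoy = TRUE, decoy_kind = kind,
          has_planted_amplicon = FALSE, amplicon_start = NA_integer_,
          amplicon_end = NA_integer_, orientation = NA_character_,
          product_length = NA_integer_,
          forward_mismatches = NA_integer_, reverse_mismatches = NA_integer_,
          duplicate_group = NA_character_, is_na_lineage = FALSE,
          length = nchar(seq), sequence = seq, stringsAsFactors = FALSE)
      }
      break
    }
    if (is.null(rec)) {
      stop(sprintf(
        "fixture self-verification failed repeatedly for accession %s (%s)",
        acc, kind), call. = FALSE)
    }
    records[[length(records) + 1L]] <- rec
  }
  truth <- do.call(rbind, records)

  # ---- duplicates ------------------------------------------------------
  planted_rows <- which(truth$kind == "planted")
  if (n_dup > 0L && length(planted_rows)) {
    for (d in seq_len(n_dup)) {
      src <- truth[planted_rows[(d - 1L) %% length(planted_rows) + 1L], ]
      acc <- new_accession()
      same_taxon <- d %% 2L == 1L
      g <- match(src$genus, genus_names)
      s_src <- which(species_names[g, ] == src$species)
      s_new <- if (same_taxon || S == 1L) s_src else
        (s_src %% S) + 1L
      dup <- src
      dup$accession <- acc
      dup$taxid <- species_ids[g, s_new]
      dup$species <- species_names[g, s_new]
      dup$kind <- "duplicate"
      dup$duplicate_group <- src$accession
      truth <- rbind(truth, dup)
    }
  }

  # ---- uninformative-lineage accessions -------------------------------
  env_ids <- character(0)
  if (n_na > 0L) {
    for (e in seq_len(n_na)) {
      g <- (e - 1L) %% G + 1L
      bp <- build_planted(g)
      acc <- new_accession()
      env_id <- as.character(next_id); next_id <- next_id + 1L
      env_ids <- c(env_ids, env_id)
      tax <- c(tax, list(data.frame(
        taxid = env_id, parent = "2", rank = "species",
        name = sprintf("uncultured eukaryote %02d", e),
        stringsAsFactors = FALSE)))
      truth <- rbind(truth, data.frame(
        accession = acc, taxid = env_id, genus = NA_character_,
        species = sprintf("uncultured eukaryote %02d", e),
        kind = "na_lineage", is_decoy = FALSE, decoy_kind = NA_character_,
        has_planted_amplicon = TRUE, amplicon_start = bp$start,
        amplicon_end = bp$end, orientation = "plus",
        product_length = bp$end - bp$start + 1L,
        forward_mismatches = bp$m_f, reverse_mismatches = bp$m_r,
        duplicate_group = NA_character_, is_na_lineage = TRUE,
        length = nchar(bp$seq), sequence = bp$seq, stringsAsFactors = FALSE))
    }
  }
  rownames(truth) <- NULL

  # ---- membership map (representative accessions) ---------------------
  membership <- data.frame(representative = character(0),
                           member = character(0), taxid = character(0),
                           stringsAsFactors = FALSE)
  if (spec$representative_fraction > 0) {
    planted_rows <- which(truth$kind == "planted")
    n_rep <- round(spec$representative_fraction * length(planted_rows))
    if (n_rep > 0L) {
      for (r in planted_rows[seq_len(n_rep)]) {
        g <- match(truth$genus[r], genus_names)
        s_src <- which(species_names[g, ] == truth$species[r])
        s_alt <- if (S == 1L) s_src else (s_src %% S) + 1L
        membership <- rbind(membership, data.frame(
          representative = truth$accession[r],
          member = c(truth$accession[r],
                     paste0(strip_version(truth$accession[r]), "m.1")),
          taxid = c(truth$taxid[r], species_ids[g, s_alt]),
          stringsAsFactors = FALSE))
      }
    }
  }

  # ---- ground-truth lineages ------------------------------------------
  tax_df <- do.call(rbind, tax)
  lineages <- data.frame(accession = truth$accession, stringsAsFactors = FALSE)
  lin_rows <- lapply(seq_len(nrow(truth)), function(i) {
    if (truth$is_na_lineage[i]) {
      l <- empty_lineage()
      l[["superkingdom"]] <- "Eukaryota"
      l[["species"]] <- truth$species[i]
      return(l)
    }
    g <- match(truth$genus[i], genus_names)
    c(superkingdom = "Eukaryota", phylum = "Chordata",
      class = "Actinopteri", order = "Synthoformes",
      family = sprintf("Synthidae_%02d", ceiling(g / 2L)),
      genus = truth$genus[i], species = truth$species[i])
  })
  lineages <- cbind(lineages,
                    as.data.frame(do.call(rbind, lin_rows),
                                  stringsAsFactors = FALSE))

  # ---- write files -----------------------------------------------------
  paths <- list(
    corpus = file.path(out_dir, "corpus.fasta"),
    acc2taxid = file.path(out_dir, "acc2taxid.tsv"),
    nodes = file.path(out_dir, "nodes.dmp"),
    names = file.path(out_dir, "names.dmp"),
    membership = file.path(out_dir, "membership.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(stats::setNames(truth$sequence, truth$accession), paths$corpus)
  a2t <- data.frame(accession = strip_version(truth$accession),
                    accession.version = truth$accession,
                    taxid = truth$taxid, gi = seq_len(nrow(truth)),
                    stringsAsFactors = FALSE)
  utils::write.table(a2t, paths$acc2taxid, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("%s\t|\t%s\t|\t%s\t|", tax_df$taxid, tax_df$parent,
                     tax_df$rank), paths$nodes)
  writeLines(sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", tax_df$taxid,
                     tax_df$name), paths$names)
  utils::write.table(membership, paths$membership, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  rec_params <- seed_params(
    min_product_length = spec$planted_amplicon_length[1L],
    max_product_length = spec$planted_amplicon_length[2L],
    max_mismatch_per_primer = max_mm,
    n_max_variants = max(length(fwd_variants), length(rev_variants)),
    rng_seed = spec$rng_seed)

  out <- structure(list(accessions = truth, lineages = lineages,
                        seed_params = rec_params, paths = paths,
                        spec = spec), class = "fixture_truth")
  jsonlite::write_json(
    list(accessions = truth[, setdiff(names(truth), "sequence")],
         lineages = lineages,
         seed_params = unclass(rec_params),
         n_accessions = nrow(truth)),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out
}

#' Load the taxonomy store belonging to a generated fixture
#' @param truth A `fixture_truth` from [generate_fixture()].
#' @return A `taxonomy_store`.
#' @export
fixture_store <- function(truth) {
  load_taxdump(truth$paths$nodes, truth$paths$names,
               acc2taxid = truth$paths$acc2taxid,
               membership = truth$paths$membership)
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf(
    "fixture_truth: %d accessions (%d planted, %d decoys, %d duplicates, %d NA-lineage)\n",
    nrow(x$accessions), sum(x$accessions$kind == "planted"),
    sum(x$accessions$is_decoy), sum(x$accessions$kind == "duplicate"),
    sum(x$accessions$is_na_lineage)))
  invisible(x)
}
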