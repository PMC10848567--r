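## Distance computation, a single-linkage cluster proxy for Barcode Index
## Numbers (BINs), and two-route taxonomy assignment: cluster taxonomy
## match first, nearest-match ("ID engine") thresholds second.
##
## The cluster proxy is NOT the RESL algorithm that mints real BINs; it
## is a documented stand-in (single linkage at 2.2% p-distance) adequate
## for library-internal accounting and simulation.

#' Classifier configuration
#'
#' @param species_max_divergence strict upper bound on divergence for a
#'   species-level match (default 0.02: "less than 2%" — 2.0% exactly is
#'   genus at most).
#' @param genus_max_divergence strict upper bound for a genus-level match
#'   (default 0.05).
#' @param bin_proxy_threshold single-linkage distance threshold of the
#'   BIN cluster proxy (default 0.022).
#' @param top_match_count number of nearest matches inspected for
#'   conflicts, ties at the cutoff included (default 20).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(species_max_divergence = 0.02,
                              genus_max_divergence = 0.05,
                              bin_proxy_threshold = 0.022,
                              top_match_count = 20L) {
  if (!(species_max_divergence < genus_max_divergence)) {
    stop("species threshold must be below genus threshold")
  }
  structure(list(species_max_divergence = species_max_divergence,
                 genus_max_divergence = genus_max_divergence,
                 bin_proxy_threshold = bin_proxy_threshold,
                 top_match_count = as.integer(top_match_count)),
            class = "classifier_config")
}

#' Reference barcode library
#'
#' @param id unique entry identifiers.
#' @param sequence IUPAC nucleotide strings.
#' @param taxonomy data frame with (a subset of) the [TAXONOMY_RANKS]
#'   columns; missing ranks are "".
#' @param cluster optional precomputed cluster labels.
#' @return a `reference_library` with an `entries` data frame.
#' @export
reference_library <- function(id, sequence, taxonomy = NULL, cluster = NA) {
  if (anyDuplicated(id)) stop("duplicate reference ids")
  if (!all(is_iupac_string(sequence))) {
    stop("reference sequences must be non-empty IUPAC strings")
  }
  n <- length(id)
  tax <- matrix("", nrow = n, ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  if (!is.null(taxonomy)) {
    for (r in intersect(names(taxonomy), TAXONOMY_RANKS)) {
      tax[, r] <- ifelse(is.na(taxonomy[[r]]), "", as.character(taxonomy[[r]]))
    }
  }
  entries <- data.frame(id = as.character(id), sequence = sequence, tax,
                        cluster = rep_len(as.character(cluster), n),
                        stringsAsFactors = FALSE)
  structure(list(entries = entries), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d entries\n", nrow(x$entries)))
  invisible(x)
}

#' Read a reference library from FASTA + taxonomy TSV
#'
#' The TSV must have an `id` column matching the FASTA record names plus
#' any of the taxonomy rank columns.
#'
#' @param fasta_path reference FASTA.
#' @param taxonomy_path taxonomy TSV; `NULL` for an unidentified library.
#' @return a [reference_library()].
#' @export
read_reference_library <- function(fasta_path, taxonomy_path = NULL) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub(" .*", "", names(x))
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tt <- read.delim(taxonomy_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!"id" %in% names(tt)) stop("taxonomy TSV needs an id column")
    tax <- tt[match(ids, tt$id), intersect(names(tt), TAXONOMY_RANKS),
              drop = FALSE]
  }
  reference_library(ids, as.character(x), taxonomy = tax)
}

#' Write a reference library to FASTA + taxonomy TSV
#'
#' @param library a [reference_library()].
#' @param fasta_path,taxonomy_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_reference_library <- function(library, fasta_path, taxonomy_path) {
  x <- Biostrings::DNAStringSet(library$entries$sequence)
  names(x) <- library$entries$id
  Biostrings::writeXStringSet(x, fasta_path)
  write.table(library$entries[, c("id", TAXONOMY_RANKS)], taxonomy_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Build a reference library from simulated barcodes
#'
#' @param barcodes data frame from [simulate_barcodes()].
#' @param identified logical: keep taxonomy (TRUE) or strip it, producing
#'   an unidentified library.
#' @return a [reference_library()].
#' @export
reference_from_barcodes <- function(barcodes, identified = TRUE) {
  reference_library(barcodes$sample_id, barcodes$sequence,
                    taxonomy = if (identified)
                      barcodes[, TAXONOMY_RANKS, drop = FALSE] else NULL)
}

#' Pairwise p-distance between two sequences
#'
#' The sequences are globally aligned with free end gaps in both
#' sequences (match +1, mismatch -1, interior gaps -2 per base), then the
#' distance is the proportion of differing sites among compared columns;
#' columns containing a gap or an ambiguous base (N or any other
#' non-A/C/G/T code) in either sequence are excluded from both numerator
#' and denominator. The measure is symmetric, non-negative, and zero on
#' identical sequences.
#'
#' @param a,b non-empty nucleotide strings.
#' @return the p-distance, a fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("p_distance requires non-empty sequences")
  cnt <- .pdist_count(a, b)
  if (cnt[["sites"]] == 0) stop("no comparable sites between sequences")
  cnt[["mismatches"]] / cnt[["sites"]]
}

## Vectorised query-vs-library distances: one ends-free alignment per
## (query, reference) pair, computed in C. Unrelated sequences can meet
## in a short chance end-overlap with spuriously low distance, so pairs
## sharing fewer than min_sites comparable sites get the maximal
## distance 1. Returns an n_query x n_ref matrix.
query_reference_distances <- function(queries, reference, min_sites = 100L) {
  refs <- reference$entries$sequence
  n <- length(queries)
  d <- matrix(NA_real_, nrow = n, ncol = length(refs))
  for (j in seq_along(refs)) {
    cnt <- .pdist_count_batch(queries, refs[j])
    d[, j] <- ifelse(cnt[, "sites"] < min_sites, 1,
                     cnt[, "mismatches"] / cnt[, "sites"])
  }
  d
}

## Nearest library entry per query: data.frame(index, distance).
nearest_reference <- function(queries, reference) {
  d <- query_reference_distances(queries, reference)
  best <- apply(d, 1, which.min)
  data.frame(index = best, distance = d[cbind(seq_along(queries), best)])
}

#' Cluster a library into BIN-proxy clusters (single linkage)
#'
#' Connected components of the graph whose edges join entries at
#' p-distance strictly below `bin_proxy_threshold`. Cluster labels are
#' deterministic: each cluster is named after its lexicographically
#' smallest member id. This proxy is not the RESL/BIN algorithm.
#'
#' @param library a [reference_library()].
#' @param cfg a [classifier_config()].
#' @param distances optional precomputed symmetric distance matrix.
#' @return character vector of cluster labels, one per entry (named by
#'   entry id).
#' @export
cluster_bins <- function(library, cfg = classifier_config(),
                         distances = NULL) {
  ids <- library$entries$id
  n <- length(ids)
  if (n == 0) stop("empty library")
  if (is.null(distances)) {
    distances <- query_reference_distances(library$entries$sequence, library)
  }
  # union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (distances[i, j] < cfg$bin_proxy_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(seq_len(n), function(i) {
    members <- ids[root == root[i]]
    sort(members)[1]
  }, character(1))
  setNames(labels, ids)
}



## Deepest rank on which all rows of `tax` agree non-emptily, respecting
## hierarchy ("lowest level without conflict"). Returns list(rank, taxonomy)
## or NULL when even the coarsest rank conflicts or is unnamed.
deepest_agreement <- function(tax) {
  agreed <- setNames(rep("", length(TAXONOMY_RANKS)), TAXONOMY_RANKS)
  deepest <- NULL
  for (r in TAXONOMY_RANKS) {
    vals <- unique(tax[[r]])
    vals <- vals[nzchar(vals)]
    if (r == "subfamily" && length(vals) == 0) next  # legitimately absent
    if (length(vals) != 1 || length(unique(tax[[r]])) != 1) break
    agreed[r] <- vals
    deepest <- r
  }
  if (is.null(deepest)) return(NULL)
  list(rank = deepest, taxonomy = agreed)
}

empty_assignment <- function(query_id) {
  structure(list(query_id = query_id, method = "none",
                 rank = NA_character_,
                 taxonomy = setNames(rep("", length(TAXONOMY_RANKS)), TAXONOMY_RANKS),
                 best_distance = NA_real_,
                 matches = character(0)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %s: %s%s\n", x$query_id, x$method,
              if (x$method == "none") "" else
                sprintf(" -> %s = %s (d = %.4f)", x$rank,
                        x$taxonomy[x$rank], x$best_distance)))
  invisible(x)
}

#' Assign taxonomy by cluster (BIN) taxonomy match
#'
#' If the query's cluster contains identified library members, the query
#' inherits the deepest rank on which all of them agree (the lowest level
#' without conflict within the cluster). A cluster with no identified
#' member returns `NULL` so the caller can fall through to the nearest
#' match route.
#'
#' @param query_id identifier recorded on the result.
#' @param cluster_members data frame of identified library entries
#'   sharing the query's cluster (columns: the taxonomy ranks, and
#'   optionally `id`, `distance`).
#' @param cfg a [classifier_config()].
#' @return an `assignment_result` with `method = "bin_match"`, or `NULL`.
#' @export
assign_bin_match <- function(query_id, cluster_members,
                             cfg = classifier_config()) {
  identified <- cluster_members[
    nzchar(cluster_members$genus) | nzchar(cluster_members$species) |
      nzchar(cluster_members$family), , drop = FALSE]
  if (nrow(identified) == 0) return(NULL)
  agree <- deepest_agreement(identified)
  if (is.null(agree)) return(NULL)
  res <- empty_assignment(query_id)
  res$method <- "bin_match"
  res$rank <- agree$rank
  res$taxonomy <- agree$taxonomy
  res$best_distance <- if ("distance" %in% names(identified))
    min(identified$distance) else NA_real_
  res$matches <- if ("id" %in% names(identified)) identified$id else character(0)
  res
}

#' Assign taxonomy by nearest-match thresholds (ID-engine rules)
#'
#' The `top_match_count` nearest references (ties at the cutoff included)
#' are inspected. The candidate rank comes from the best distance:
#' species when strictly below `species_max_divergence`, genus when
#' strictly below `genus_max_divergence`, otherwise none. Among the top
#' matches within the governing threshold, the assigned rank is the
#' deepest conflict-free rank, never deeper than the candidate rank.
#'
#' @param query query sequence string.
#' @param query_id identifier recorded on the result.
#' @param library a [reference_library()].
#' @param cfg a [classifier_config()].
#' @param distances optional precomputed distances from the query to each
#'   library entry.
#' @return an `assignment_result` with method `id_engine` or `none`.
#' @export
assign_id_engine <- function(query, query_id = "query", library,
                             cfg = classifier_config(), distances = NULL) {
  if (nrow(library$entries) == 0) stop("empty library")
  if (is.null(distances)) {
    distances <- query_reference_distances(query, library)[1, ]
  }
  res <- empty_assignment(query_id)
  best <- min(distances)
  res$best_distance <- best
  if (best >= cfg$genus_max_divergence) return(res)
  governing <- if (best < cfg$species_max_divergence)
    cfg$species_max_divergence else cfg$genus_max_divergence
  candidate_rank <- if (best < cfg$species_max_divergence) "species" else "genus"

  ord <- order(distances)
  k <- min(cfg$top_match_count, length(ord))
  cutoff <- distances[ord[k]]
  top <- ord[distances[ord] <= cutoff]            # ties included
  top <- top[distances[top] < governing]          # within governing threshold
  members <- library$entries[top, , drop = FALSE]
  agree <- deepest_agreement(members)
  if (is.null(agree)) return(res)
  # truncate to candidate rank
  max_i <- match(candidate_rank, TAXONOMY_RANKS)
  got_i <- match(agree$rank, TAXONOMY_RANKS)
  if (got_i > max_i) {
    agree$rank <- candidate_rank
    agree$taxonomy[TAXONOMY_RANKS[(max_i + 1):length(TAXONOMY_RANKS)]] <- ""
  }
  if (!nzchar(agree$taxonomy[agree$rank])) return(res)
  res$method <- "id_engine"
  res$rank <- agree$rank
  res$taxonomy <- agree$taxonomy
  res$matches <- members$id
  res
}

#' Assign taxonomy to queries via both routes
#'
#' Queries and library are clustered together with the BIN proxy; each
#' query is first offered a cluster taxonomy match (inheriting the
#' conflict-free taxonomy of identified cluster co-members) and only
#' queries unresolved by that route are sent to the nearest-match ID
#' engine rules. No query is assigned by both routes.
#'
#' @param queries data frame with `id` and `sequence` columns (or a named
#'   character vector of sequences).
#' @param library an identified [reference_library()].
#' @param cfg a [classifier_config()].
#' @return list with `results` (list of `assignment_result`) and
#'   `summary` (method x rank count matrix, see [assignment_report()]).
#' @export
assign_all <- function(queries, library, cfg = classifier_config()) {
  if (is.character(queries)) {
    queries <- data.frame(id = names(queries), sequence = unname(queries),
                          stringsAsFactors = FALSE)
  }
  nq <- nrow(queries)
  qd <- if (nq) query_reference_distances(queries$sequence, library) else
    matrix(0, 0, nrow(library$entries))
  # joint clustering: distances among library entries and queries
  all_ids <- c(library$entries$id, queries$id)
  nl <- nrow(library$entries)
  full <- matrix(1, nl + nq, nl + nq)
  full[seq_len(nl), seq_len(nl)] <-
    query_reference_distances(library$entries$sequence, library)
  if (nq) {
    full[nl + seq_len(nq), seq_len(nl)] <- qd
    full[seq_len(nl), nl + seq_len(nq)] <- t(qd)
    if (nq > 1) {
      qq <- query_reference_distances(
        queries$sequence,
        reference_library(queries$id, queries$sequence))
      full[nl + seq_len(nq), nl + seq_len(nq)] <- qq
    } else {
      full[nl + 1, nl + 1] <- 0
    }
  }
  # internal ids keep the joint library collision-free even when a query
  # shares an id with a reference entry
  joint <- reference_library(paste0(c(rep("ref::", nl), rep("query::", nq)),
                                    all_ids),
                             c(library$entries$sequence, queries$sequence))
  clusters <- cluster_bins(joint, cfg, distances = full)

  results <- vector("list", nq)
  for (i in seq_len(nq)) {
    qcl <- clusters[nl + i]
    co <- which(clusters[seq_len(nl)] == qcl)
    members <- library$entries[co, , drop = FALSE]
    if (nrow(members)) members$distance <- qd[i, co]
    r <- assign_bin_match(queries$id[i], members, cfg)
    if (is.null(r)) {
      r <- assign_id_engine(queries$sequence[i], queries$id[i], library,
                            cfg, distances = qd[i, ])
    }
    results[[i]] <- r
  }
  names(results) <- queries$id
  summary <- matrix(0L, nrow = 2, ncol = 2,
                    dimnames = list(c("bin_match", "id_engine"),
                                    c("genus", "species")))
  for (r in results) {
    if (r$method == "none") next
    rank <- if (identical(r$rank, "species")) "species" else "genus"
    summary[r$method, rank] <- summary[r$method, rank] + 1L
  }
  list(results = results, summary = summary)
}

#' Write assignment results to TSV
#'
#' Columns: `query_id`, `method`, `rank`, `taxon`, `distance`.
#'
#' @param results the `results` element of [assign_all()].
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_assignments <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(query_id = r$query_id, method = r$method,
               rank = ifelse(is.na(r$rank), "", r$rank),
               taxon = if (is.na(r$rank)) "" else r$taxonomy[r$rank],
               distance = r$best_distance, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
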