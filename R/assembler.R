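## The assembly pipeline: quality filter -> UMI demultiplex ->
## order-level taxonomy screen -> amplicon assignment -> alignment-free
## positioning -> positional consensus with N fill.

#' Pipeline configuration
#'
#' Houses every numeric threshold of the assembly pipeline.
#'
#' @param min_qv minimum mean read quality value (Phred; default 20).
#' @param min_read_length minimum read length in bp (default 100).
#' @param min_predicted_accuracy minimum predicted read accuracy used
#'   when converting accuracies to QV (default 0.99, i.e. QV 20).
#' @param umi_tolerance mismatches tolerated when decoding a UMI tag
#'   (default 1).
#' @param order_filter_max_distance maximum p-distance to the nearest
#'   reference for a read to be classifiable (default 0.20).
#' @param screen_min_sites minimum number of aligned sites between a read
#'   and its nearest reference for the read to be classifiable (default
#'   50); shorter chance alignments are `unclassifiable`.
#' @param primer_max_mismatch_frac primer-match tolerance as a fraction
#'   of primer length (default 0.10).
#' @param consensus_min_depth minimum per-column depth to call a base
#'   (default 1).
#' @param acceptable_barcode_bp minimum non-N length of an acceptable
#'   barcode; default 301, i.e. strictly more than 300 bp.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_qv = 20,
                            min_read_length = 100L,
                            min_predicted_accuracy = 0.99,
                            umi_tolerance = 1L,
                            order_filter_max_distance = 0.20,
                            screen_min_sites = 50L,
                            primer_max_mismatch_frac = 0.10,
                            consensus_min_depth = 1L,
                            acceptable_barcode_bp = 301L) {
  stopifnot(min_qv >= 0, min_read_length >= 0,
            min_predicted_accuracy > 0, min_predicted_accuracy <= 1,
            umi_tolerance >= 0,
            order_filter_max_distance >= 0, order_filter_max_distance <= 1,
            screen_min_sites >= 1,
            primer_max_mismatch_frac >= 0, primer_max_mismatch_frac < 1,
            consensus_min_depth >= 1, acceptable_barcode_bp >= 1)
  structure(list(min_qv = min_qv,
                 min_read_length = as.integer(min_read_length),
                 min_predicted_accuracy = min_predicted_accuracy,
                 umi_tolerance = as.integer(umi_tolerance),
                 order_filter_max_distance = order_filter_max_distance,
                 screen_min_sites = as.integer(screen_min_sites),
                 primer_max_mismatch_frac = primer_max_mismatch_frac,
                 consensus_min_depth = as.integer(consensus_min_depth),
                 acceptable_barcode_bp = as.integer(acceptable_barcode_bp)),
            class = "pipeline_config")
}

empty_log <- function() {
  data.frame(id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Filter reads on quality and length
#'
#' A read is kept iff its mean QV is at least `min_qv` and its length at
#' least `min_read_length`. The mean QV is the filtering statistic
#' (consistent with predicted-accuracy style per-read quality summaries).
#'
#' @param reads data frame with `id`, `sequence`, `mean_qv`.
#' @param cfg a [pipeline_config()].
#' @return list with `kept` (read data frame) and `rejected`
#'   (data frame `id`, `reason` in `too_short`/`low_qv`).
#' @export
filter_reads <- function(reads, cfg = pipeline_config()) {
  if (nrow(reads) == 0) return(list(kept = reads, rejected = empty_log()))
  len <- nchar(reads$sequence)
  too_short <- len < cfg$min_read_length
  low_qv <- !too_short & reads$mean_qv < cfg$min_qv
  keep <- !too_short & !low_qv
  list(kept = reads[keep, , drop = FALSE],
       rejected = data.frame(
         id = reads$id[!keep],
         reason = ifelse(too_short[!keep], "too_short", "low_qv"),
         stringsAsFactors = FALSE))
}

## Decode observed tag words against one direction's 96 tags.
## Returns the unique tag index within `tol` mismatches, else NA.
decode_tags <- function(obs, tags_vec, tol) {
  n <- length(obs)
  if (n == 0) return(integer(0))
  L <- nchar(tags_vec[1])
  ok <- nchar(obs) == L
  res <- rep(NA_integer_, n)
  if (!any(ok)) return(res)
  om <- seq_char_matrix(obs[ok], L)
  best <- rep(L + 1L, sum(ok))
  best_i <- rep(NA_integer_, sum(ok))
  n_at_best <- rep(0L, sum(ok))
  for (t in seq_along(tags_vec)) {
    d <- rowSums(om != matrix(strsplit(tags_vec[t], "", fixed = TRUE)[[1]],
                              nrow = nrow(om), ncol = L, byrow = TRUE))
    lower <- d < best
    tie <- d == best
    best_i[lower] <- t
    n_at_best[lower] <- 1L
    n_at_best[tie] <- n_at_best[tie] + 1L
    best[lower] <- d[lower]
  }
  hit <- best <= tol & n_at_best == 1L
  res[ok][hit] <- best_i[hit]
  res
}

#' Demultiplex reads to wells via their terminal UMI tags
#'
#' Both read orientations are tried: a read is assigned iff, on exactly
#' one strand (or consistently on both), its first `tag_length` bases
#' decode uniquely to a forward tag within `umi_tolerance` mismatches,
#' the reverse complement of its last `tag_length` bases decodes to a
#' reverse tag, and that (forward, reverse) pair is a well in the tag
#' set's assignment. Every read lands in exactly one well bin or in the
#' unassigned bin — the result is a partition.
#'
#' @param reads read data frame.
#' @param tags a `tag_set`.
#' @param cfg a [pipeline_config()].
#' @param plate optional `plate_array`; when given, wells are translated
#'   to sample IDs and reads hitting wells with no specimen are
#'   unassigned (`empty_well`), except the control well, which keeps its
#'   own bin.
#' @return list with `assignments` (data frame `id`, `well`, `sample_id`,
#'   `orientation`, `reason`; `reason` is `""` for assigned reads) and
#'   `bins` (reads split by sample ID / well label).
#' @export
demultiplex <- function(reads, tags, cfg = pipeline_config(), plate = NULL) {
  n <- nrow(reads)
  L <- tags$tag_length
  lookup <- tag_pair_lookup(tags)
  decode_strand <- function(seqs) {
    f <- decode_tags(substr(seqs, 1, L), tags$forward_tags, cfg$umi_tolerance)
    r <- decode_tags(revcomp(substr(seqs, pmax(1, nchar(seqs) - L + 1),
                                    nchar(seqs))),
                     tags$reverse_tags, cfg$umi_tolerance)
    well <- rep(NA_integer_, length(seqs))
    both <- !is.na(f) & !is.na(r)
    well[both] <- lookup[paste(f[both], r[both])]
    list(f = f, r = r, well = well, decoded = both)
  }
  if (n == 0) {
    assignments <- data.frame(id = character(0), well = character(0),
                              sample_id = character(0),
                              orientation = character(0),
                              reason = character(0), stringsAsFactors = FALSE)
    return(list(assignments = assignments, bins = list()))
  }
  fwd <- decode_strand(reads$sequence)
  rev <- decode_strand(revcomp(reads$sequence))
  well <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)
  reason <- rep("tag_unmatched", n)
  f_ok <- !is.na(fwd$well); r_ok <- !is.na(rev$well)
  well[f_ok] <- fwd$well[f_ok]; orientation[f_ok] <- "forward"
  well[!f_ok & r_ok] <- rev$well[!f_ok & r_ok]
  orientation[!f_ok & r_ok] <- "reverse"
  conflict <- f_ok & r_ok & fwd$well != rev$well
  well[conflict] <- NA; orientation[conflict] <- NA
  reason[conflict] <- "ambiguous_orientation"
  pair_conflict <- is.na(well) & !conflict &
    ((fwd$decoded & is.na(fwd$well)) | (rev$decoded & is.na(rev$well)))
  reason[pair_conflict] <- "tag_conflict"
  reason[!is.na(well)] <- ""

  wl <- well_label(all_wells())
  well_lab <- ifelse(is.na(well), NA_character_, wl[well])
  sample_id <- well_lab
  if (!is.null(plate)) {
    ids <- setNames(rep(NA_character_, 96), wl)
    if (nrow(plate$specimens)) {
      sw <- parse_sample_id(plate$specimens$sample_id)
      ids[well_label(sw)] <- plate$specimens$sample_id
    }
    ctrl <- well_label(plate$control_well)
    ids[ctrl] <- format_sample_id(plate$plate_code, plate$control_well)
    sample_id <- ifelse(is.na(well_lab), NA_character_, ids[well_lab])
    drop <- !is.na(well_lab) & is.na(sample_id)
    reason[drop] <- "empty_well"
    well_lab[drop] <- NA
    orientation[drop] <- NA
  }
  assignments <- data.frame(id = reads$id, well = well_lab,
                            sample_id = sample_id,
                            orientation = orientation,
                            reason = reason, stringsAsFactors = FALSE)
  assigned <- !is.na(assignments$sample_id)
  bins <- split(reads[assigned, , drop = FALSE],
                assignments$sample_id[assigned])
  list(assignments = assignments, bins = bins)
}

#' Screen reads against an expected taxonomic order
#'
#' Each read (already oriented to the barcode strand) is classified to
#' the order of its nearest reference by p-distance; it is kept iff that
#' order equals `expected_order` and the distance does not exceed
#' `order_filter_max_distance`. Non-target reads (`wrong_order`) and
#' reads too far from every reference (`unclassifiable`) are discarded.
#'
#' @param reads read data frame (oriented).
#' @param expected_order order name the sample should contain.
#' @param reference a [reference_library()] with at least one entry per
#'   represented order.
#' @param cfg a [pipeline_config()].
#' @return list with `kept` and `discarded` (`id`, `reason`).
#' @export
taxonomy_screen <- function(reads, expected_order, reference,
                            cfg = pipeline_config()) {
  if (nrow(reference$entries) == 0) stop("empty reference library")
  if (nrow(reads) == 0) return(list(kept = reads, discarded = empty_log()))
  reason <- screen_reasons(reads$sequence,
                           rep_len(expected_order, nrow(reads)),
                           reference, cfg)
  keep <- reason == ""
  list(kept = reads[keep, , drop = FALSE],
       discarded = data.frame(id = reads$id[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
}

## Vectorised screen core: "" = kept, else wrong_order / unclassifiable.
## Reads are compared to each reference by local alignment (reads carry
## technical flanks and cover only part of the frame); the nearest
## reference is the one with the smallest local p-distance among
## alignments spanning at least screen_min_sites sites. A read whose best
## alignment is shorter than screen_min_sites, or farther than
## order_filter_max_distance, is unclassifiable.
screen_reasons <- function(seqs, expected_orders, reference, cfg) {
  if (length(seqs) == 0) return(character(0))
  uniq <- unique(seqs)               # amplicon reads repeat at depth > 1
  refs <- reference$entries$sequence
  d <- matrix(1, nrow = length(uniq), ncol = length(refs))
  for (j in seq_along(refs)) {
    cnt <- .pdist_local_batch(uniq, refs[j])
    ok <- cnt[, "sites"] >= cfg$screen_min_sites
    d[ok, j] <- cnt[ok, "mismatches"] / cnt[ok, "sites"]
  }
  nearest <- apply(d, 1, which.min)
  best <- d[cbind(seq_along(uniq), nearest)]
  i <- match(seqs, uniq)
  order_of <- reference$entries$order[nearest[i]]
  ifelse(best[i] > cfg$order_filter_max_distance, "unclassifiable",
         ifelse(order_of != expected_orders, "wrong_order", ""))
}

## Best approximate occurrence of `pat` in `subject`.
## Exact match via fixed-string search first (the common case for
## high-accuracy reads), then mismatch-tolerant scans of increasing k,
## finally an indel-tolerant scan at full tolerance.
best_primer_hit <- function(pat, subject, tol) {
  p <- regexpr(pat, subject, fixed = TRUE)
  if (p > 0) {
    return(list(start = as.integer(p), end = as.integer(p) + nchar(pat) - 1L,
                mismatches = 0L))
  }
  if (tol == 0) return(NULL)
  subj <- Biostrings::DNAString(subject)
  ppat <- Biostrings::DNAString(pat)
  for (k in seq_len(tol)) {
    m <- Biostrings::matchPattern(ppat, subj, max.mismatch = k, fixed = FALSE)
    if (length(m) > 0) {
      return(list(start = Biostrings::start(m)[1], end = Biostrings::end(m)[1],
                  mismatches = k))
    }
  }
  m <- Biostrings::matchPattern(ppat, subj, max.mismatch = tol,
                                with.indels = TRUE, fixed = FALSE)
  if (length(m) > 0) {
    return(list(start = Biostrings::start(m)[1], end = Biostrings::end(m)[1],
                mismatches = tol))
  }
  NULL
}

#' Assign a read to its amplicon via the locus primers
#'
#' Both strands are scanned for every amplicon's forward primer and the
#' reverse complement of its reverse primer, within a mismatch tolerance
#' of `primer_max_mismatch_frac` of the primer length. The amplicon and
#' strand with the fewest total primer mismatches win; an exact tie
#' between amplicons is returned as unassigned (`ambiguous`).
#'
#' @param read a single-row read data frame, or a sequence string.
#' @param panel an `amplicon_panel`.
#' @param cfg a [pipeline_config()].
#' @param orientation optionally restrict the scan to one strand
#'   (`"forward"` or `"reverse"`), e.g. when known from demultiplexing.
#' @return list with `amplicon` (id or `NA`), `orientation`, `insert`
#'   (the primer-trimmed insert on the barcode strand) and `reason`
#'   (`""`, `no_primer_match` or `ambiguous`).
#' @export
assign_amplicon <- function(read, panel, cfg = pipeline_config(),
                            orientation = NULL) {
  seq <- if (is.character(read)) read else read$sequence
  strands <- if (is.null(orientation)) c("forward", "reverse") else orientation
  tol_for <- function(p) floor(cfg$primer_max_mismatch_frac * nchar(p))
  hits <- list()
  for (st in strands) {
    s <- if (st == "forward") seq else revcomp(seq)
    for (a in panel$amplicons) {
      hf <- best_primer_hit(a$fwd$sequence, s, tol_for(a$fwd$sequence))
      if (is.null(hf)) next
      hr <- best_primer_hit(revcomp(a$rev$sequence), s, tol_for(a$rev$sequence))
      if (is.null(hr) || hr$start <= hf$end) next
      hits[[length(hits) + 1L]] <- list(
        amplicon = a$id, orientation = st,
        score = hf$mismatches + hr$mismatches,
        insert = substr(s, hf$end + 1L, hr$start - 1L))
    }
  }
  if (length(hits) == 0) {
    return(list(amplicon = NA_character_, orientation = NA_character_,
                insert = NA_character_, reason = "no_primer_match"))
  }
  scores <- vapply(hits, `[[`, numeric(1), "score")
  best <- which(scores == min(scores))
  if (length(unique(vapply(hits[best], `[[`, character(1), "amplicon"))) > 1) {
    return(list(amplicon = NA_character_, orientation = NA_character_,
                insert = NA_character_, reason = "ambiguous"))
  }
  h <- hits[[best[1]]]
  list(amplicon = h$amplicon, orientation = h$orientation,
       insert = h$insert, reason = "")
}

## Vectorised best-hit search of one primer over many sequences:
## exact fixed-string search first (the common case for high-accuracy
## reads), then mismatch-tolerant scans of increasing k for the
## remainder. Returns per-sequence start/end/mismatch count (NA = none).
primer_hits_batch <- function(pat, seqs, tol) {
  n <- length(seqs)
  start <- rep(NA_integer_, n)
  mm <- rep(NA_integer_, n)
  r <- regexpr(pat, seqs, fixed = TRUE)
  hit <- r > 0
  start[hit] <- r[hit]
  mm[hit] <- 0L
  todo <- which(!hit)
  if (length(todo) && tol > 0) {
    sset <- Biostrings::DNAStringSet(seqs[todo])
    for (k in seq_len(tol)) {
      if (length(todo) == 0) break
      m <- Biostrings::vmatchPattern(pat, sset, max.mismatch = k,
                                     fixed = FALSE)
      cnt <- lengths(m)
      found <- which(cnt > 0)
      if (length(found)) {
        start[todo[found]] <- vapply(found, function(i)
          BiocGenerics::start(m[[i]])[1], integer(1))
        mm[todo[found]] <- k
        todo <- todo[-found]
        sset <- sset[-found]
      }
    }
  }
  list(start = start, end = start + nchar(pat) - 1L, mm = mm)
}

## Batch amplicon assignment for reads already oriented to the barcode
## strand. Same semantics as assign_amplicon restricted to the forward
## strand: fewest total primer mismatches wins, ties are ambiguous.
assign_amplicons_batch <- function(seqs, panel, cfg) {
  n <- length(seqs)
  best_score <- rep(Inf, n)
  best_amp <- rep(NA_character_, n)
  best_insert <- rep(NA_character_, n)
  tie <- rep(FALSE, n)
  for (a in panel$amplicons) {
    tf <- floor(cfg$primer_max_mismatch_frac * nchar(a$fwd$sequence))
    tr <- floor(cfg$primer_max_mismatch_frac * nchar(a$rev$sequence))
    hf <- primer_hits_batch(a$fwd$sequence, seqs, tf)
    hr <- primer_hits_batch(revcomp(a$rev$sequence), seqs, tr)
    ok <- !is.na(hf$start) & !is.na(hr$start) & hr$start > hf$end
    score <- hf$mm + hr$mm
    better <- ok & score < best_score
    equal <- ok & score == best_score & !is.na(best_amp)
    tie[equal] <- TRUE
    tie[better] <- FALSE
    best_amp[better] <- a$id
    best_insert[better] <- substr(seqs[better], hf$end[better] + 1L,
                                  hr$start[better] - 1L)
    best_score[better] <- score[better]
  }
  reason <- ifelse(is.na(best_amp), "no_primer_match",
                   ifelse(tie, "ambiguous", ""))
  best_amp[reason != ""] <- NA_character_
  best_insert[reason != ""] <- NA_character_
  data.frame(amplicon_id = best_amp, insert = best_insert, reason = reason,
             stringsAsFactors = FALSE)
}

#' Position primer-trimmed fragments on the barcode frame
#'
#' Alignment-free and reference-free: each fragment is anchored at its
#' amplicon's frame start; its frame interval runs for the fragment's
#' actual length (capped at the frame end). No pairwise alignment is
#' performed, so an indel inside a fragment shifts its downstream bases
#' rather than being gapped out — a deliberate fidelity/simplicity
#' trade-off that matters only at appreciable indel rates.
#'
#' @param assigned data frame with columns `read_id`, `sample_id`,
#'   `amplicon_id`, `insert` (barcode-strand, primer/tag trimmed).
#' @param panel an `amplicon_panel`.
#' @return list with `fragments` (data frame `read_id`, `sample_id`,
#'   `amplicon_id`, `sequence`, `frame_start`, `frame_end`) and
#'   `dropped` (`id`, `reason`) for empty fragments.
#' @export
position_fragments <- function(assigned, panel) {
  if (nrow(assigned) == 0) {
    return(list(fragments = data.frame(
      read_id = character(0), sample_id = character(0),
      amplicon_id = character(0), sequence = character(0),
      frame_start = integer(0), frame_end = integer(0),
      stringsAsFactors = FALSE), dropped = empty_log()))
  }
  amp_start <- vapply(panel$amplicons, `[[`, integer(1), "start")
  starts <- amp_start[assigned$amplicon_id]
  len <- nchar(assigned$insert)
  empty <- is.na(assigned$insert) | len == 0
  ends <- pmin(starts + len, panel$frame_length)
  seqs <- substr(assigned$insert, 1L, ends - starts)
  frag <- data.frame(read_id = assigned$read_id[!empty],
                     sample_id = assigned$sample_id[!empty],
                     amplicon_id = assigned$amplicon_id[!empty],
                     sequence = seqs[!empty],
                     frame_start = starts[!empty],
                     frame_end = ends[!empty],
                     stringsAsFactors = FALSE)
  dropped <- data.frame(id = assigned$read_id[empty],
                        reason = rep("empty_fragment", sum(empty)),
                        stringsAsFactors = FALSE)
  list(fragments = frag, dropped = dropped)
}

#' Call a positional consensus barcode for one sample
#'
#' Per frame column, the majority base among covering fragments is
#' emitted when the column depth reaches `consensus_min_depth`; ties emit
#' N. The consensus spans from the first to the last covered column, and
#' any zero-coverage column strictly inside that span is filled with N so
#' the sequence is contiguous. Flags: `no_reads` when no fragment covers
#' any column, `short` when the non-N length is below
#' `acceptable_barcode_bp`.
#'
#' @param fragments positioned fragments for one sample (see
#'   [position_fragments()]).
#' @param panel an `amplicon_panel`.
#' @param cfg a [pipeline_config()].
#' @param sample_id sample identifier recorded on the result.
#' @return a `consensus_barcode`: list with `sample_id`, `sequence`,
#'   `nonN_length`, `span` (0-based half-open), `coverage` (full-frame
#'   depth vector) and `flags`.
#' @export
call_consensus <- function(fragments, panel, cfg = pipeline_config(),
                           sample_id = NA_character_) {
  fl <- panel$frame_length
  counts <- matrix(0L, nrow = 4, ncol = fl,
                   dimnames = list(DNA_BASES, NULL))
  cov <- integer(fl)
  for (i in seq_len(nrow(fragments))) {
    ch <- strsplit(fragments$sequence[i], "", fixed = TRUE)[[1]]
    s0 <- fragments$frame_start[i]
    npos <- min(length(ch), fl - s0)
    if (npos <= 0) next
    cols <- s0 + seq_len(npos)
    cov[cols] <- cov[cols] + 1L
    keep <- ch[seq_len(npos)] %in% DNA_BASES
    if (any(keep)) {
      # within one fragment each column appears once, so vectorised
      # increment is safe
      idx <- cbind(match(ch[seq_len(npos)][keep], DNA_BASES), cols[keep])
      counts[idx] <- counts[idx] + 1L
    }
  }
  covered <- which(cov > 0L)
  if (length(covered) == 0) {
    return(structure(list(sample_id = sample_id, sequence = "",
                          nonN_length = 0L, span = c(0L, 0L),
                          coverage = cov, flags = "no_reads"),
                     class = "consensus_barcode"))
  }
  span <- c(min(covered) - 1L, max(covered))  # 0-based half-open
  cols <- (span[1] + 1L):span[2]
  call_col <- function(j) {
    if (cov[j] < cfg$consensus_min_depth) return("N")
    cc <- counts[, j]
    if (all(cc == 0L)) return("N")
    top <- which(cc == max(cc))
    if (length(top) > 1L) "N" else DNA_BASES[top]
  }
  seq_chars <- vapply(cols, call_col, character(1))
  sequence <- paste(seq_chars, collapse = "")
  nonN <- sum(seq_chars != "N")
  flags <- character(0)
  if (nonN < cfg$acceptable_barcode_bp) flags <- c(flags, "short")
  structure(list(sample_id = sample_id, sequence = sequence,
                 nonN_length = as.integer(nonN), span = span,
                 coverage = cov,
                 flags = if (length(flags)) flags else character(0)),
            class = "consensus_barcode")
}

#' @export
print.consensus_barcode <- function(x, ...) {
  cat(sprintf("<consensus_barcode> %s: span [%d, %d), %d non-N bp%s\n",
              x$sample_id, x$span[1], x$span[2], x$nonN_length,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Validate a consensus against its expected order
#'
#' The consensus is compared to the reference library; if the nearest
#' reference's order differs from the specimen's expected order, the
#' `contaminated` flag is added. All-N or read-less barcodes skip
#' validation.
#'
#' @param barcode a `consensus_barcode`.
#' @param expected_order the specimen's recorded order.
#' @param reference a [reference_library()].
#' @param cfg a [pipeline_config()].
#' @return the barcode with updated `flags`, plus `nearest_id`,
#'   `nearest_order` and `nearest_distance` fields.
#' @export
validate_consensus <- function(barcode, expected_order, reference,
                               cfg = pipeline_config()) {
  if (nrow(reference$entries) == 0) stop("empty reference library")
  if ("no_reads" %in% barcode$flags || barcode$nonN_length == 0) {
    if (!"no_reads" %in% barcode$flags) {
      barcode$flags <- c(barcode$flags, "no_reads")
    }
    return(barcode)
  }
  nr <- nearest_reference(barcode$sequence, reference)
  i <- nr$index[1]
  barcode$nearest_id <- reference$entries$id[i]
  barcode$nearest_order <- reference$entries$order[i]
  barcode$nearest_distance <- nr$distance[1]
  # flag only classifiable mismatches: a consensus too far from every
  # reference cannot implicate a foreign order
  if (!identical(reference$entries$order[i], expected_order) &&
      nzchar(expected_order) &&
      barcode$nearest_distance <= cfg$order_filter_max_distance) {
    barcode$flags <- unique(c(barcode$flags, "contaminated"))
  }
  barcode
}

#' Run the full assembly pipeline for one plate
#'
#' Composes the six stages — quality filter, UMI demultiplex, taxonomy
#' screen, amplicon assignment, positioning, consensus — and returns one
#' consensus barcode per specimen plus a per-stage accounting report. At
#' every stage, kept + rejected equals the stage input.
#'
#' @param reads a FASTQ path or a read data frame (`id`, `sequence`,
#'   `mean_qv`).
#' @param plate a `plate_array`.
#' @param panel an `amplicon_panel`.
#' @param tags a `tag_set`.
#' @param reference optional [reference_library()]; `NULL` skips the
#'   taxonomy screen and contamination validation.
#' @param cfg a [pipeline_config()].
#' @return list with `barcodes` (named list of `consensus_barcode`, one
#'   per specimen), `report` (stage counts), `assignments` (demultiplex
#'   table) and `logs` (per-stage rejection tables).
#' @export
run_pipeline <- function(reads, plate, panel, tags, reference = NULL,
                         cfg = pipeline_config()) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  n_in <- nrow(reads)
  filt <- filter_reads(reads, cfg)
  dmx <- demultiplex(filt$kept, tags, cfg, plate = plate)

  specimens <- plate$specimens
  exp_order <- setNames(specimens$order, specimens$sample_id)
  asg <- dmx$assignments
  keep <- !is.na(asg$sample_id) & asg$sample_id %in% specimens$sample_id
  pool <- data.frame(
    read_id = asg$id[keep],
    sample_id = asg$sample_id[keep],
    sequence = ifelse(asg$orientation[keep] == "reverse",
                      revcomp(filt$kept$sequence[keep]),
                      filt$kept$sequence[keep]),
    stringsAsFactors = FALSE)

  logs <- list(filter = filt$rejected,
               demultiplex = asg[asg$reason != "", c("id", "reason")],
               screen = empty_log(), amplicon = empty_log(),
               position = empty_log())

  if (!is.null(reference) && nrow(pool)) {
    reason <- screen_reasons(pool$sequence, exp_order[pool$sample_id],
                             reference, cfg)
    logs$screen <- data.frame(id = pool$read_id[reason != ""],
                              reason = reason[reason != ""],
                              stringsAsFactors = FALSE)
    pool <- pool[reason == "", , drop = FALSE]
  }
  n_screened <- nrow(pool)

  amp <- assign_amplicons_batch(pool$sequence, panel, cfg)
  logs$amplicon <- data.frame(id = pool$read_id[amp$reason != ""],
                              reason = amp$reason[amp$reason != ""],
                              stringsAsFactors = FALSE)
  ok <- amp$reason == ""
  assigned <- data.frame(read_id = pool$read_id[ok],
                         sample_id = pool$sample_id[ok],
                         amplicon_id = amp$amplicon_id[ok],
                         insert = amp$insert[ok],
                         stringsAsFactors = FALSE)
  pos <- position_fragments(assigned, panel)
  logs$position <- pos$dropped
  frag_by_sample <- split(pos$fragments,
                          factor(pos$fragments$sample_id,
                                 levels = specimens$sample_id))
  barcodes <- lapply(specimens$sample_id, function(sid) {
    bc <- call_consensus(frag_by_sample[[sid]], panel, cfg, sample_id = sid)
    if (!is.null(reference)) {
      bc <- validate_consensus(bc, exp_order[[sid]], reference, cfg)
    }
    bc
  })
  names(barcodes) <- specimens$sample_id
  report <- data.frame(
    stage = c("input", "filtered", "demultiplexed", "screened",
              "amplicon_assigned"),
    reads = c(n_in, nrow(filt$kept), sum(asg$reason == ""),
              n_screened, sum(ok)),
    stringsAsFactors = FALSE)
  list(barcodes = barcodes, report = report,
       assignments = asg, logs = logs)
}

#' Write consensus barcodes to FASTA plus flag table
#'
#' @param barcodes named list of `consensus_barcode`.
#' @param fasta_path output FASTA (one record per sample).
#' @param flags_path optional TSV of `sample_id`, `nonN_length`, `flags`.
#' @return `fasta_path`, invisibly.
#' @export
write_consensus_fasta <- function(barcodes, fasta_path, flags_path = NULL) {
  seqs <- vapply(barcodes, `[[`, character(1), "sequence")
  keep <- nzchar(seqs)
  x <- Biostrings::DNAStringSet(seqs[keep])
  names(x) <- vapply(barcodes[keep], `[[`, character(1), "sample_id")
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(flags_path)) {
    df <- data.frame(
      sample_id = vapply(barcodes, `[[`, character(1), "sample_id"),
      nonN_length = vapply(barcodes, `[[`, integer(1), "nonN_length"),
      flags = vapply(barcodes, function(b)
        paste(b$flags, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    write.table(df, flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
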