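## Amplicon panels and UMI tag sets.
##
## All coordinates are 0-based, half-open, on a canonical 658-bp COI
## barcode frame. Primer sequences for the shipped presets are documented
## placeholders for simulation: real panels supply their own via the
## YAML/JSON schema (see load_panel).

COI_FRAME_LENGTH <- 658L

#' Construct a primer
#'
#' @param name primer name.
#' @param sequence IUPAC nucleotide string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param anneal_start 0-based annealing position on the barcode frame.
#' @param frame_length frame length used for bounds checking.
#' @return a `primer` list.
#' @export
primer <- function(name, sequence, orientation,
                   anneal_start = 0L, frame_length = COI_FRAME_LENGTH) {
  sequence <- toupper(sequence)
  if (!is_iupac_string(sequence)) {
    stop("primer ", name, ": sequence must be a non-empty IUPAC string")
  }
  orientation <- match.arg(orientation, c("forward", "reverse"))
  anneal_start <- as.integer(anneal_start)
  if (anneal_start < 0L || anneal_start >= frame_length) {
    stop("primer ", name, ": anneal_start out of frame [0, ",
         frame_length, ")")
  }
  structure(list(name = name, sequence = sequence,
                 orientation = orientation, anneal_start = anneal_start),
            class = "primer")
}

#' Construct an amplicon
#'
#' @param id amplicon identifier.
#' @param start,end 0-based half-open insert interval on the barcode
#'   frame; insert length is `end - start`.
#' @param fwd,rev the flanking [primer()]s.
#' @param frame_length frame length for bounds checking.
#' @return an `amplicon` list.
#' @export
amplicon <- function(id, start, end, fwd, rev,
                     frame_length = COI_FRAME_LENGTH) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end ||
      end > frame_length) {
    stop("amplicon ", id, ": invalid interval [", start, ", ", end,
         ") on frame of length ", frame_length)
  }
  structure(list(id = as.character(id), start = start, end = end,
                 fwd = fwd, rev = rev),
            class = "amplicon")
}

#' Construct an amplicon panel
#'
#' A tiling scheme over the barcode frame. The panel records whether the
#' union of amplicon insert intervals covers the whole frame
#' (`coverage = "complete"`) or not (`"partial"`).
#'
#' @param name panel name.
#' @param amplicons list of [amplicon()]s with unique ids.
#' @param frame_length barcode frame length in bp (default 658).
#' @return an `amplicon_panel` object.
#' @export
amplicon_panel <- function(name, amplicons,
                           frame_length = COI_FRAME_LENGTH) {
  ids <- vapply(amplicons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate amplicon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- vapply(amplicons, function(a) a$end > frame_length, logical(1))
  if (any(bad)) {
    stop("amplicons out of frame: ", paste(ids[bad], collapse = ", "))
  }
  covered <- logical(frame_length)
  for (a in amplicons) covered[(a$start + 1L):a$end] <- TRUE
  structure(list(name = name,
                 frame_length = as.integer(frame_length),
                 amplicons = setNames(amplicons, ids),
                 coverage = if (all(covered)) "complete" else "partial"),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("<amplicon_panel> %s: %d amplicon(s) on a %d-bp frame, coverage %s\n",
              x$name, length(x$amplicons), x$frame_length, x$coverage))
  for (a in x$amplicons) {
    cat(sprintf("  %s [%d, %d) insert %d bp\n", a$id, a$start, a$end,
                a$end - a$start))
  }
  invisible(x)
}

## Placeholder flanking primers for the shipped presets. These are fixed,
## non-degenerate 20-mers that do not occur in the COI frame; they stand
## in for the published primer cocktails, which are configuration data,
## not code.
preset_primer_pairs <- function(n) {
  fwd <- c("ACGGTCATGCAATTCGACTG", "TGCAACGTTAGCCATGACTC",
           "GATCCGTAACTGGCATCAGT", "CCATGTTCGAACGGATTAGC",
           "TGGACTCAGCGTATACCAGT", "AGCTTCGGTCAATGCACTGA")
  rev <- c("TCAGGCTAACGTCATGGATC", "GTACCATCGGCTTGAACAGT",
           "CAGTTGCGAATCCATGGTCA", "TTGGCAGATCGCATACGTCA",
           "ACGATCCTGAGCGTTACAGT", "GCATCAGTTACGGACTCGAT")
  if (n > length(fwd)) stop("at most ", length(fwd), " preset primer pairs")
  list(fwd = fwd[seq_len(n)], rev = rev[seq_len(n)])
}

## Two overlapping Sanger amplicons with insert lengths 307 and 407 bp
## spanning the 658-bp frame.
panel_sanger2 <- function() {
  p <- preset_primer_pairs(2)
  amplicon_panel("sanger2", list(
    amplicon("S1", 0L, 307L,
             primer(paste0(p$fwd[1], "_F"), p$fwd[1], "forward", 0L),
             primer(paste0(p$rev[1], "_R"), p$rev[1], "reverse", 306L)),
    amplicon("S2", 251L, 658L,
             primer(paste0(p$fwd[2], "_F"), p$fwd[2], "forward", 251L),
             primer(paste0(p$rev[2], "_R"), p$rev[2], "reverse", 657L))
  ))
}

## Six short overlapping amplicons tiling the whole frame, the layout used
## for failure tracking of degraded specimens.
panel_ngs_tiled <- function() {
  starts <- c(0L, 110L, 220L, 330L, 440L, 550L)
  ends   <- c(120L, 230L, 340L, 450L, 560L, 658L)
  p <- preset_primer_pairs(6)
  amps <- lapply(seq_along(starts), function(i) {
    amplicon(paste0("T", i), starts[i], ends[i],
             primer(sprintf("ngs_F%d", i), p$fwd[i], "forward", starts[i]),
             primer(sprintf("ngs_R%d", i), p$rev[i], "reverse", ends[i] - 1L))
  })
  amplicon_panel("ngs_tiled", amps)
}

#' Load an amplicon panel
#'
#' Accepts either a built-in preset name or the path of a YAML/JSON panel
#' description. Presets:
#' \describe{
#'   \item{`"sanger2"`}{two overlapping amplicons, insert lengths 307 and
#'     407 bp, as in classical two-fragment Sanger barcoding.}
#'   \item{`"ngs_tiled"`}{six short overlapping amplicons tiling the full
#'     658-bp frame, the degraded-specimen failure-tracking layout.}
#' }
#'
#' The file schema is a mapping with `name`, optional `frame_length`
#' (default 658) and a list `amplicons`, each with `id`, `start`, `end`
#' (0-based, half-open) and `fwd`/`rev` mappings carrying `name`,
#' `sequence` and `anneal_start`.
#'
#' @param path preset name or config file path.
#' @return an `amplicon_panel`.
#' @export
load_panel <- function(path) {
  if (path == "sanger2") return(panel_sanger2())
  if (path == "ngs_tiled") return(panel_ngs_tiled())
  if (!file.exists(path)) {
    stop("unknown preset or missing panel file: ", path)
  }
  cfg <- read_config_file(path)
  frame_length <- as.integer(cfg$frame_length %||% COI_FRAME_LENGTH)
  if (is.null(cfg$amplicons)) stop("panel config has no amplicons: ", path)
  amps <- lapply(cfg$amplicons, function(a) {
    amplicon(a$id, a$start, a$end,
             primer(a$fwd$name %||% paste0(a$id, "_F"), a$fwd$sequence,
                    "forward", a$fwd$anneal_start %||% a$start,
                    frame_length),
             primer(a$rev$name %||% paste0(a$id, "_R"), a$rev$sequence,
                    "reverse", a$rev$anneal_start %||% (a$end - 1),
                    frame_length),
             frame_length)
  })
  amplicon_panel(cfg$name %||% tools::file_path_sans_ext(basename(path)),
                 amps, frame_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

## ---- UMI tag sets ---------------------------------------------------------

#' Construct and validate a UMI tag set
#'
#' Asymmetric dual indexing: 96 forward and 96 reverse sample tags, one
#' (forward, reverse) pair per well. For a decoder that accepts up to
#' `tolerance` mismatches to decode uniquely, tags within each direction
#' must be pairwise at Hamming distance at least `2 * tolerance + 1`;
#' this is verified at construction and violations name the closest pair.
#'
#' @param forward_tags,reverse_tags character vectors of 96 equal-length
#'   tags each, over A/C/G/T.
#' @param well_assignment integer matrix `96 x 2` mapping the row-major
#'   well index to (forward tag index, reverse tag index); default pairs
#'   well i with forward tag i and reverse tag i.
#' @param tolerance mismatch tolerance the set must support (default 1).
#' @return a `tag_set` object.
#' @export
tag_set <- function(forward_tags, reverse_tags,
                    well_assignment = cbind(1:96, 1:96), tolerance = 1L) {
  for (side in list(forward = forward_tags, reverse = reverse_tags)) NULL
  check_side <- function(tags, label) {
    if (length(tags) != 96) stop(label, ": expected 96 tags, got ", length(tags))
    if (length(unique(nchar(tags))) != 1) stop(label, ": tags differ in length")
    if (!all(is_dna_string(tags))) stop(label, ": tags must be A/C/G/T strings")
    dup <- unique(tags[duplicated(tags)])
    if (length(dup)) stop(label, ": duplicate tags: ", paste(dup, collapse = ", "))
    min_required <- 2L * as.integer(tolerance) + 1L
    cm <- seq_char_matrix(tags, nchar(tags[1]))
    for (i in seq_len(95)) {
      d <- rowSums(cm[(i + 1):96, , drop = FALSE] !=
                     matrix(cm[i, ], nrow = 96 - i, ncol = ncol(cm), byrow = TRUE))
      if (any(d < min_required)) {
        j <- i + which.min(d)
        stop(label, ": tags ", tags[i], " and ", tags[j],
             " are at Hamming distance ", min(d),
             " < ", min_required, " required for tolerance ", tolerance)
      }
    }
  }
  check_side(forward_tags, "forward tags")
  check_side(reverse_tags, "reverse tags")
  wa <- matrix(as.integer(well_assignment), ncol = 2)
  if (nrow(wa) != 96 || any(wa < 1L) || any(wa > 96L)) {
    stop("well_assignment must be a 96 x 2 matrix of tag indices in 1..96")
  }
  if (anyDuplicated(paste(wa[, 1], wa[, 2]))) {
    stop("well_assignment reuses a (forward, reverse) tag pair")
  }
  structure(list(forward_tags = forward_tags, reverse_tags = reverse_tags,
                 well_assignment = wa, tag_length = nchar(forward_tags[1]),
                 tolerance = as.integer(tolerance)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> 96 + 96 %d-bp tags, tolerance %d\n",
              x$tag_length, x$tolerance))
  invisible(x)
}

#' Generate a valid tag set deterministically
#'
#' Greedy rejection sampling under a fixed seed: random tags are accepted
#' only when at Hamming distance >= `2 * tolerance + 1` from every tag
#' already accepted in the same direction. With 8-bp tags and tolerance 1
#' the 96 + 96 tags are found essentially immediately.
#'
#' @param tag_length tag length in bp (default 8).
#' @param tolerance mismatch tolerance to support (default 1).
#' @param seed RNG seed (fixed default so the shipped set is stable).
#' @return a `tag_set`.
#' @export
make_tagset <- function(tag_length = 8L, tolerance = 1L, seed = 20170901L) {
  withr::local_seed(seed)
  min_dist <- 2L * tolerance + 1L
  draw_side <- function() {
    tags <- character(0)
    mat <- matrix("", nrow = 0, ncol = tag_length)
    while (length(tags) < 96) {
      cand <- sample(DNA_BASES, tag_length, replace = TRUE)
      if (nrow(mat) == 0 ||
          all(rowSums(mat != matrix(cand, nrow = nrow(mat),
                                    ncol = tag_length, byrow = TRUE)) >= min_dist)) {
        tags <- c(tags, paste(cand, collapse = ""))
        mat <- rbind(mat, cand)
      }
    }
    tags
  }
  tag_set(draw_side(), draw_side(), tolerance = tolerance)
}

#' Load a tag set from a YAML/JSON config
#'
#' Schema: mapping with `forward_tags` and `reverse_tags` (96 strings
#' each) and optional `well_assignment` (list of 96 two-element
#' `[forward, reverse]` index pairs, row-major well order).
#'
#' @param path config file path.
#' @param tolerance mismatch tolerance the set must support (default 1).
#' @return a validated `tag_set`.
#' @export
load_tagset <- function(path, tolerance = 1L) {
  cfg <- read_config_file(path)
  wa <- if (is.null(cfg$well_assignment)) cbind(1:96, 1:96) else
    do.call(rbind, lapply(cfg$well_assignment, unlist))
  tag_set(unlist(cfg$forward_tags), unlist(cfg$reverse_tags),
          well_assignment = wa, tolerance = tolerance)
}

#' Write a tag set to a YAML config
#'
#' @param tags a `tag_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tagset <- function(tags, path) {
  yaml::write_yaml(list(forward_tags = as.list(tags$forward_tags),
                        reverse_tags = as.list(tags$reverse_tags),
                        well_assignment = lapply(seq_len(96), function(i)
                          as.list(tags$well_assignment[i, ]))),
                   path)
  invisible(path)
}

## Tag pair -> well index lookup ("" keyed by "f r").
tag_pair_lookup <- function(tags) {
  setNames(seq_len(96),
           paste(tags$well_assignment[, 1], tags$well_assignment[, 2]))
}
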