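## Synthetic data generation: true barcodes with a shallow taxonomic
## structure, an age-driven amplicon dropout model, and tagged noisy reads
## whose structure matches what the assembler expects:
##   UMI_f + fwd_primer + insert + revcomp(rev_primer) + revcomp(UMI_r)

#' Degradation and sequencing-error model
#'
#' Amplifiable template molecules fragment over time; the model treats
#' each amplicon of each specimen as surviving with probability
#' `2^(-age / half_life_years)` (exponential decay in specimen age, the
#' standard fragmentation assumption; the per-amplicon half-life is a
#' deliberately simple summary of fragment-length decay). Reads from
#' surviving amplicons carry independent per-base substitutions at
#' `base_error_rate` and indels at `indel_rate` (geometric insertion
#' lengths), reflecting already-polished circular consensus reads rather
#' than raw instrument error. Defaults are illustrative, not estimated
#' from any dataset.
#'
#' @param half_life_years per-amplicon survival half-life (> 0; `Inf`
#'   disables dropout).
#' @param base_error_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel probability in `[0, 1)`.
#' @return a `degradation_model` list.
#' @export
degradation_model <- function(half_life_years = 30,
                              base_error_rate = 0.005,
                              indel_rate = 0.0005) {
  if (!(half_life_years > 0)) stop("half_life_years must be positive")
  for (r in c(base_error_rate, indel_rate)) {
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  }
  structure(list(half_life_years = half_life_years,
                 base_error_rate = base_error_rate,
                 indel_rate = indel_rate),
            class = "degradation_model")
}

#' Simulate true specimen barcodes with taxonomic structure
#'
#' Sequences evolve from a single root: one ancestor per genus (mutated
#' from the root at `genus_divergence` per site), one per species within
#' a genus (`species_divergence` from the genus ancestor), and one
#' barcode per specimen (`individual_divergence` from the species
#' ancestor). With the defaults, two conspecific barcodes differ at
#' roughly `2 * individual_divergence` (~1%, i.e. below the 2% species
#' threshold) while two genera differ at roughly `2 * genus_divergence`
#' (~12%, well above the 5% genus threshold) — the separations the
#' threshold classifier assumes.
#'
#' Specimens are laid out row-major over as many 95-specimen plates as
#' needed (the control well is skipped) and receive collection years
#' drawn uniformly from `collection_years`.
#'
#' @param n number of specimens.
#' @param n_genera number of genera (default ~ one genus per 4 specimens).
#' @param species_per_genus species simulated within each genus.
#' @param genus_divergence,species_divergence,individual_divergence
#'   per-site substitution probabilities applied at each level;
#'   `species_divergence` must be smaller than `genus_divergence`.
#' @param order_name taxonomic order assigned to every specimen.
#' @param collection_years inclusive year range specimens are drawn from.
#' @param frame_length barcode length in bp (default 658).
#' @param plate_codes plate codes to lay specimens onto (generated when
#'   `NULL`).
#' @param control_well reserved well skipped on every plate.
#' @param seed RNG seed; same seed, same output.
#' @return data frame with columns `sample_id`, `sequence`, the
#'   [TAXONOMY_RANKS], and `collection_year`.
#' @export
simulate_barcodes <- function(n, n_genera = max(1L, ceiling(n / 4)),
                              species_per_genus = 2L,
                              genus_divergence = 0.06,
                              species_divergence = 0.015,
                              individual_divergence = 0.005,
                              order_name = "Diptera",
                              collection_years = c(1897L, 2017L),
                              frame_length = COI_FRAME_LENGTH,
                              plate_codes = NULL,
                              control_well = well_address("H", 12),
                              seed = 1L) {
  if (n < 0) stop("n must be non-negative")
  if (species_divergence >= genus_divergence) {
    stop("species_divergence must be below genus_divergence")
  }
  empty <- data.frame(sample_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS) empty[[r]] <- character(0)
  empty$collection_year <- integer(0)
  if (n == 0) return(empty)
  withr::local_seed(seed)

  root <- random_dna(1, frame_length)
  genus_anc <- vapply(seq_len(n_genera), function(g)
    mutate_seq(root, genus_divergence), character(1))
  sp_anc <- lapply(seq_len(n_genera), function(g)
    vapply(seq_len(species_per_genus), function(s)
      mutate_seq(genus_anc[g], species_divergence), character(1)))

  genus_of <- rep_len(seq_len(n_genera), n)
  species_of <- unlist(lapply(seq_len(n_genera), function(g)
    rep_len(seq_len(species_per_genus), sum(genus_of == g))))
  seqs <- vapply(seq_len(n), function(i)
    mutate_seq(sp_anc[[genus_of[i]]][species_of[i]], individual_divergence),
    character(1))

  n_plates <- ceiling(n / 95)
  if (is.null(plate_codes)) {
    plate_codes <- sprintf("CCDB-%05d", 31120L + seq_len(n_plates) - 1L)
  }
  wells <- all_wells()
  usable <- well_label(wells) != well_label(control_well)
  well_seq <- wells[usable, , drop = FALSE]
  plate_i <- ((seq_len(n) - 1L) %/% 95L) + 1L
  well_i <- ((seq_len(n) - 1L) %% 95L) + 1L
  sample_id <- format_sample_id(plate_codes[plate_i],
                                well_seq[well_i, , drop = FALSE])

  genus_name <- sprintf("Genus%02d", genus_of)
  fam <- sprintf("Family%02d", ((genus_of - 1L) %/% 5L) + 1L)
  df <- data.frame(
    sample_id = sample_id, sequence = seqs,
    phylum = "Arthropoda", class = "Insecta", order = order_name,
    family = fam, subfamily = "",
    genus = genus_name,
    species = sprintf("%s sp%02d", genus_name, species_of),
    collection_year = {
      years <- collection_years[1]:collection_years[2]
      years[sample.int(length(years), n, replace = TRUE)]
    },
    stringsAsFactors = FALSE
  )
  df
}

#' Specimen records for simulated barcodes
#'
#' @param barcodes output of [simulate_barcodes()].
#' @return a `specimen_record` with the simulated taxonomy and years.
#' @export
barcode_records <- function(barcodes) {
  specimen_record(barcodes$sample_id,
                  taxonomy = barcodes[, TAXONOMY_RANKS, drop = FALSE],
                  collection_year = barcodes$collection_year)
}

## Sequencing noise is applied to the insert only; tag and primer bases
## are emitted clean. Errors there would only destroy reads (Hamming
## decoding and primer matching absorb or reject them), adding nothing to
## what the decode tests cover; see the methods vignette.
noisy_insert <- function(insert, model) {
  s <- mutate_seq(insert, model$base_error_rate)
  if (model$indel_rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (b in ch) {
    u <- runif(1)
    if (u < model$indel_rate / 2) {
      next                                   # deletion
    } else if (u < model$indel_rate) {
      ins_len <- 1L + stats::rgeom(1, 0.5)   # insertion, geometric length
      out <- c(out, b, sample(DNA_BASES, ins_len, replace = TRUE))
    } else {
      out <- c(out, b)
    }
  }
  paste(out, collapse = "")
}

qv_for_model <- function(model) {
  err <- model$base_error_rate + model$indel_rate
  if (err <= 0) 93 else min(93, round(-10 * log10(err)))
}

#' Simulate tagged amplicon reads for one plate of specimens
#'
#' For every specimen and every panel amplicon, the amplicon survives
#' degradation with probability `2^(-age / half_life_years)` where age is
#' `analysis_year - collection_year`. Each surviving amplicon emits
#' `depth` reads: the insert is copied from the true barcode over the
#' amplicon's frame interval, substitution/indel noise is applied, and
#' the read is wrapped in its locus primers and the well's forward and
#' reverse UMI tags. About half of all reads are emitted
#' reverse-complemented.
#'
#' @param barcodes data frame from [simulate_barcodes()]; at most 95 rows,
#'   all on one plate, wells distinct and not the control well.
#' @param panel an `amplicon_panel`.
#' @param tags a `tag_set`; each barcode's well must map to a tag pair.
#' @param model a [degradation_model()].
#' @param depth reads emitted per surviving amplicon.
#' @param analysis_year year used to convert collection year to age.
#' @param seed RNG seed.
#' @return list with `reads` (data frame: `id`, `sequence`, `mean_qv`)
#'   and `truth` (data frame: `read_id`, `sample_id`, `amplicon_id`).
#' @export
simulate_reads <- function(barcodes, panel, tags, model,
                           depth = 3L, analysis_year = 2017L, seed = 1L) {
  withr::local_seed(seed)
  if (nrow(barcodes) > 95) stop("simulate_reads handles one plate (<= 95 specimens)")
  parsed <- parse_sample_id(barcodes$sample_id)
  if (length(unique(parsed$plate_code)) > 1) {
    stop("barcodes span multiple plates; simulate per plate")
  }
  widx <- well_index(parsed)
  if (anyDuplicated(widx)) stop("duplicate wells among barcodes")
  qv <- qv_for_model(model)
  age <- pmax(0L, analysis_year - barcodes$collection_year)
  reads <- list(); truth <- list(); k <- 0L
  for (i in seq_len(nrow(barcodes))) {
    pair <- tags$well_assignment[widx[i], ]
    umi_f <- tags$forward_tags[pair[1]]
    umi_r <- tags$reverse_tags[pair[2]]
    p_survive <- 2^(-age[i] / model$half_life_years)
    for (a in panel$amplicons) {
      if (runif(1) >= p_survive) next
      insert <- substr(barcodes$sequence[i], a$start + 1L, a$end)
      for (d in seq_len(depth)) {
        k <- k + 1L
        body <- paste0(umi_f, a$fwd$sequence, noisy_insert(insert, model),
                       revcomp(a$rev$sequence), revcomp(umi_r))
        if (runif(1) < 0.5) body <- revcomp(body)
        id <- sprintf("read%06d", k)
        reads[[k]] <- data.frame(id = id, sequence = body, mean_qv = qv,
                                 stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(read_id = id,
                                 sample_id = barcodes$sample_id[i],
                                 amplicon_id = a$id,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  empty_reads <- data.frame(id = character(0), sequence = character(0),
                            mean_qv = numeric(0), stringsAsFactors = FALSE)
  empty_truth <- data.frame(read_id = character(0), sample_id = character(0),
                            amplicon_id = character(0), stringsAsFactors = FALSE)
  list(reads = if (k) do.call(rbind, reads) else empty_reads,
       truth = if (k) do.call(rbind, truth) else empty_truth)
}

#' Simulate negative-control well reads
#'
#' A clean control emits no reads. With `contamination_rate > 0`, reads
#' are copied from a randomly chosen donor specimen's template but tagged
#' with the control well's tag pair — the situation the contamination
#' flag is designed to catch.
#'
#' @param tags a `tag_set`.
#' @param panel an `amplicon_panel`.
#' @param donors data frame of candidate donor barcodes (as from
#'   [simulate_barcodes()]); required when `contamination_rate > 0`.
#' @param contamination_rate probability that each amplicon is
#'   contaminated (0 = clean control).
#' @param depth reads per contaminated amplicon.
#' @param control_well the control square (default H12).
#' @param seed RNG seed.
#' @return list with `reads` and `truth` (`sample_id` names the donor).
#' @export
simulate_negative_control <- function(tags, panel, donors = NULL,
                                      contamination_rate = 0, depth = 5L,
                                      control_well = well_address("H", 12),
                                      seed = 1L) {
  withr::local_seed(seed)
  empty <- list(reads = data.frame(id = character(0), sequence = character(0),
                                   mean_qv = numeric(0), stringsAsFactors = FALSE),
                truth = data.frame(read_id = character(0), sample_id = character(0),
                                   amplicon_id = character(0),
                                   stringsAsFactors = FALSE))
  if (contamination_rate <= 0) return(empty)
  if (is.null(donors) || nrow(donors) == 0) {
    stop("contamination_rate > 0 requires a non-empty donor pool")
  }
  pair <- tags$well_assignment[well_index(control_well), ]
  umi_f <- tags$forward_tags[pair[1]]
  umi_r <- tags$reverse_tags[pair[2]]
  reads <- list(); truth <- list(); k <- 0L
  for (a in panel$amplicons) {
    if (runif(1) >= contamination_rate) next
    donor <- donors[sample(nrow(donors), 1), ]
    insert <- substr(donor$sequence, a$start + 1L, a$end)
    for (d in seq_len(depth)) {
      k <- k + 1L
      id <- sprintf("ctrl%06d", k)
      reads[[k]] <- data.frame(
        id = id,
        sequence = paste0(umi_f, a$fwd$sequence, insert,
                          revcomp(a$rev$sequence), revcomp(umi_r)),
        mean_qv = 93, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(read_id = id, sample_id = donor$sample_id,
                               amplicon_id = a$id, stringsAsFactors = FALSE)
    }
  }
  if (k == 0) return(empty)
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' Every base receives the read's mean quality value.
#'
#' @param reads data frame with `id`, `sequence`, `mean_qv`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  q <- vapply(seq_len(nrow(reads)), function(i) {
    paste(rep(rawToChar(as.raw(33L + min(93L, max(0L, round(reads$mean_qv[i]))))),
              nchar(reads$sequence[i])), collapse = "")
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(q))
  invisible(path)
}

#' Read FASTQ into the pipeline's read table
#'
#' @param path FASTQ path (Phred+33).
#' @return data frame with `id`, `sequence`, `mean_qv` (mean per-base
#'   Phred score).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(x) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      mean_qv = numeric(0), stringsAsFactors = FALSE))
  }
  qv <- suppressWarnings(
    vapply(as(Biostrings::quality(x), "IntegerList"), mean, numeric(1)))
  # plain character payload; dropping quality metadata is intended
  seqs <- suppressWarnings(as.character(x))
  data.frame(id = sub(" .*", "", names(x)),
             sequence = seqs,
             mean_qv = qv, stringsAsFactors = FALSE)
}
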