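make_reads <- function(seqs, qv = 93) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             mean_qv = rep_len(qv, length(seqs)), stringsAsFactors = FALSE)
}

empty_assigned <- function() {
  data.frame(read_id = character(0), sample_id = character(0),
             amplicon_id = character(0), insert = character(0),
             stringsAsFactors = FALSE)
}

test_that("read filtering applies QV and length thresholds with reasons", {
  cfg <- pipeline_config()
  reads <- data.frame(
    id = c("a", "b", "c"),
    sequence = c(random_seq(99, 1), random_seq(150, 2), random_seq(100, 3)),
    mean_qv = c(40, 19, 20), stringsAsFactors = FALSE)
  res <- filter_reads(reads, cfg)
  expect_equal(res$kept$id, "c")
  expect_equal(res$rejected$reason[res$rejected$id == "a"], "too_short")
  expect_equal(res$rejected$reason[res$rejected$id == "b"], "low_qv")
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(reads))

  empty <- filter_reads(reads[0, ], cfg)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("demultiplexing decodes tags within tolerance and partitions reads", {
  tags <- shared_tags()
  cfg <- pipeline_config()
  ins <- random_seq(120, 21)
  exact <- tagged_read(paste0(ins, random_seq(538, 22)),
                       load_panel("ngs_tiled")$amplicons[[1]], tags, 1)
  # 1 mismatch in the forward tag still decodes (tolerance 1)
  one_mm <- exact
  substr(one_mm, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                  substr(exact, 1, 1))[1]
  # forward tag of well 1 paired with reverse tag of well 2: no such well
  pair1 <- tags$well_assignment[1, ]
  pair2 <- tags$well_assignment[2, ]
  conflict <- paste0(tags$forward_tags[pair1[1]], ins,
                     revcomp(tags$reverse_tags[pair2[2]]))
  junk <- random_seq(150, 23)
  res <- demultiplex(make_reads(c(exact, one_mm, conflict, junk,
                                  revcomp(exact))), tags, cfg)
  a <- res$assignments
  expect_equal(a$well[1], "A01")
  expect_equal(a$well[2], "A01")
  expect_equal(a$reason[3], "tag_conflict")
  expect_equal(a$reason[4], "tag_unmatched")
  expect_equal(a$well[5], "A01")
  expect_equal(a$orientation[5], "reverse")
  # partition: every read either assigned to exactly one well or unassigned
  expect_true(all(xor(is.na(a$well), a$reason == "")))
})

test_that("taxonomy screen keeps expected-order reads and rejects others", {
  bc <- simulate_barcodes(8, n_genera = 4, seed = 31)
  out <- simulate_barcodes(4, n_genera = 2, order_name = "Lepidoptera",
                           seed = 32)
  ref <- reference_library(
    c(bc$sample_id[c(1, 3)], "lep1"),
    c(bc$sequence[c(1, 3)], out$sequence[1]),
    taxonomy = data.frame(order = c("Diptera", "Diptera", "Lepidoptera")))
  reads <- make_reads(c(substr(bc$sequence[1], 101, 260),
                        substr(out$sequence[1], 101, 260),
                        random_seq(160, 33)))
  res <- taxonomy_screen(reads, "Diptera", ref)
  expect_equal(res$kept$id, "r001")
  expect_equal(res$discarded$reason[res$discarded$id == "r002"],
               "wrong_order")
  expect_equal(res$discarded$reason[res$discarded$id == "r003"],
               "unclassifiable")
  expect_error(taxonomy_screen(reads, "Diptera",
                               reference_library(character(0), character(0))),
               "empty")
})

test_that("amplicon assignment finds the primer pair on either strand", {
  panel <- load_panel("ngs_tiled")
  tags <- shared_tags()
  bc <- random_seq(658, 41)
  rd <- tagged_read(bc, panel$amplicons[["T3"]], tags, 5)
  fwd <- assign_amplicon(rd, panel)
  expect_equal(fwd$amplicon, "T3")
  expect_equal(fwd$orientation, "forward")
  expect_equal(fwd$insert, substr(bc, 221, 340))
  rev <- assign_amplicon(revcomp(rd), panel)
  expect_equal(rev$amplicon, "T3")
  expect_equal(rev$orientation, "reverse")
  expect_equal(rev$insert, substr(bc, 221, 340))

  # both primer pairs of two amplicons equally present: ambiguous
  a1 <- panel$amplicons[[1]]; a2 <- panel$amplicons[[2]]
  chimera <- paste0(a1$fwd$sequence, random_seq(50, 42),
                    revcomp(a1$rev$sequence),
                    a2$fwd$sequence, random_seq(50, 43),
                    revcomp(a2$rev$sequence))
  amb <- assign_amplicon(chimera, panel)
  expect_equal(amb$reason, "ambiguous")
  none <- assign_amplicon(random_seq(150, 44), panel)
  expect_equal(none$reason, "no_primer_match")
})

test_that("fragments anchor at their amplicon start without realignment", {
  panel <- load_panel("ngs_tiled")
  assigned <- data.frame(
    read_id = c("x", "y", "z"),
    sample_id = "s",
    amplicon_id = c("T2", "T2", "T2"),
    insert = c(random_seq(120, 51), random_seq(118, 52), ""),
    stringsAsFactors = FALSE)
  res <- position_fragments(assigned, panel)
  expect_equal(res$fragments$frame_start, c(110L, 110L))
  expect_equal(res$fragments$frame_end, c(230L, 228L))  # 2-bp deletion: shorter
  expect_equal(res$dropped$id, "z")
  expect_equal(res$dropped$reason, "empty_fragment")
})

test_that("consensus majority, tie and N-fill rules match the column oracle", {
  panel <- amplicon_panel("toy", list(
    amplicon("L", 0, 100,
             primer("LF", "ACGGTCATGCAATTCGACTG", "forward", 0),
             primer("LR", "TCAGGCTAACGTCATGGATC", "reverse", 99),
             frame_length = 300),
    amplicon("R", 200, 300,
             primer("RF", "TGCAACGTTAGCCATGACTC", "forward", 200),
             primer("RR", "GTACCATCGGCTTGAACAGT", "reverse", 299),
             frame_length = 300)), frame_length = 300)
  left <- random_seq(100, 61)
  right <- random_seq(100, 62)
  frags <- data.frame(read_id = c("a", "b"), sample_id = "s",
                      amplicon_id = c("L", "R"),
                      sequence = c(left, right),
                      frame_start = c(0L, 200L), frame_end = c(100L, 300L),
                      stringsAsFactors = FALSE)
  bc <- call_consensus(frags, panel, sample_id = "s")
  expect_equal(nchar(bc$sequence), 300)
  expect_equal(substr(bc$sequence, 1, 100), left)
  expect_equal(substr(bc$sequence, 101, 200), paste(rep("N", 100), collapse = ""))
  expect_equal(substr(bc$sequence, 201, 300), right)
  expect_equal(bc$nonN_length, 200L)
  expect_true("short" %in% bc$flags)

  # single fragment: consensus equals the fragment
  one <- call_consensus(frags[1, ], panel, sample_id = "s")
  expect_equal(one$sequence, left)
  expect_equal(one$span, c(0L, 100L))

  # column oracle: enumerate all compositions of up to 3 votes
  majority_oracle <- function(bases) {
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else "N"
  }
  bases <- c("A", "C", "G", "T")
  combos <- c(lapply(bases, identity),
              apply(expand.grid(bases, bases), 1, as.character,
                    simplify = FALSE),
              apply(expand.grid(bases, bases, bases), 1, as.character,
                    simplify = FALSE))
  for (combo in combos) {
    f <- data.frame(read_id = seq_along(combo), sample_id = "s",
                    amplicon_id = "L", sequence = combo,
                    frame_start = 0L, frame_end = 1L,
                    stringsAsFactors = FALSE)
    got <- call_consensus(f, panel, sample_id = "s")
    expect_equal(got$sequence, majority_oracle(combo),
                 label = paste(combo, collapse = ""))
  }

  # no fragments at all
  none <- call_consensus(position_fragments(empty_assigned(), panel)$fragments,
                         panel, sample_id = "s")
  expect_true("no_reads" %in% none$flags)
  expect_equal(none$nonN_length, 0L)
})

test_that("consensus validation flags foreign-order assemblies", {
  bc <- simulate_barcodes(4, n_genera = 2, seed = 71)
  out <- simulate_barcodes(2, n_genera = 1, order_name = "Lepidoptera",
                           seed = 72)
  ref <- reference_library(
    c("d1", "lep1"), c(bc$sequence[1], out$sequence[1]),
    taxonomy = data.frame(order = c("Diptera", "Lepidoptera")))
  good <- structure(list(sample_id = "s", sequence = bc$sequence[2],
                         nonN_length = 658L, span = c(0L, 658L),
                         coverage = rep(1L, 658), flags = character(0)),
                    class = "consensus_barcode")
  v <- validate_consensus(good, "Diptera", ref)
  expect_false("contaminated" %in% v$flags)
  bad <- good
  bad$sequence <- out$sequence[2]
  v2 <- validate_consensus(bad, "Diptera", ref)
  expect_true("contaminated" %in% v2$flags)
  allN <- good
  allN$sequence <- ""
  allN$nonN_length <- 0L
  v3 <- validate_consensus(allN, "Diptera", ref)
  expect_true("no_reads" %in% v3$flags)
  expect_null(v3$nearest_id)
})

test_that("the pipeline conserves reads at every stage and handles empty input", {
  panel <- load_panel("ngs_tiled")
  tags <- shared_tags()
  bc <- simulate_barcodes(10, seed = 81, collection_years = c(2015L, 2017L))
  plate <- plate_array(parse_sample_id(bc$sample_id)$plate_code[1],
                       barcode_records(bc))
  sim <- simulate_reads(bc, panel, tags,
                        degradation_model(Inf, 0.005, 0), depth = 3,
                        seed = 82)
  res <- run_pipeline(sim$reads, plate, panel, tags)
  rep <- setNames(res$report$reads, res$report$stage)
  expect_equal(rep[["input"]],
               rep[["filtered"]] + nrow(res$logs$filter))
  expect_equal(rep[["filtered"]],
               rep[["demultiplexed"]] + nrow(res$logs$demultiplex))
  expect_equal(rep[["screened"]],
               rep[["amplicon_assigned"]] + nrow(res$logs$amplicon))
  # demultiplexing is a partition: no read in two bins
  total_binned <- sum(!is.na(res$assignments$sample_id))
  expect_equal(total_binned + sum(res$assignments$reason != ""),
               nrow(sim$reads))

  empty <- run_pipeline(make_reads(character(0)), plate, panel, tags)
  expect_true(all(vapply(empty$barcodes, function(b)
    "no_reads" %in% b$flags, logical(1))))
})

test_that("noiseless reads reassemble every barcode exactly", {
  panel <- load_panel("ngs_tiled")
  tags <- shared_tags()
  bc <- simulate_barcodes(12, seed = 91, collection_years = c(2017L, 2017L))
  plate <- plate_array(parse_sample_id(bc$sample_id)$plate_code[1],
                       barcode_records(bc))
  sim <- simulate_reads(bc, panel, tags, degradation_model(Inf, 0, 0),
                        depth = 2, seed = 92)
  res <- run_pipeline(sim$reads, plate, panel, tags)
  for (i in seq_len(nrow(bc))) {
    expect_identical(res$barcodes[[bc$sample_id[i]]]$sequence,
                     bc$sequence[i])
  }
})

test_that("consensus FASTA and flag table are written for downstream use", {
  panel <- load_panel("ngs_tiled")
  tags <- shared_tags()
  bc <- simulate_barcodes(3, seed = 95, collection_years = c(2017L, 2017L))
  plate <- plate_array(parse_sample_id(bc$sample_id)$plate_code[1],
                       barcode_records(bc))
  sim <- simulate_reads(bc, panel, tags, degradation_model(Inf, 0, 0),
                        depth = 1, seed = 96)
  res <- run_pipeline(sim$reads, plate, panel, tags)
  fa <- tempfile(fileext = ".fasta")
  fl <- tempfile(fileext = ".tsv")
  write_consensus_fasta(res$barcodes, fa, fl)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 3)
  expect_equal(unname(as.character(back[bc$sample_id[1]])), bc$sequence[1])
  flags <- read.delim(fl)
  expect_equal(nrow(flags), 3)
  expect_true(all(flags$nonN_length == 658))
})
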