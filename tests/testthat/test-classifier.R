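test_that("p-distance counts mismatches over comparable sites only", {
  a <- random_seq(100, 101)
  expect_equal(p_distance(a, a), 0)
  b <- substitute_at(a, c(10, 60))
  expect_equal(p_distance(a, b), 0.02)
  # 10 Ns and 3 mismatches elsewhere: 3 / 90 (independent site counter)
  c_ <- substitute_at(a, c(5, 25, 45))
  cc <- strsplit(c_, "")[[1]]
  cc[81:90] <- "N"
  c_ <- paste(cc, collapse = "")
  expect_equal(p_distance(a, c_), 3 / 90)
  expect_equal(p_distance(a, c_), pdist_oracle(a, c_))
  expect_error(p_distance("", a), "non-empty")
  expect_error(p_distance(paste(rep("N", 50), collapse = ""), a),
               "no comparable sites")

  # premetric over random pairs: non-negative, symmetric, identity of
  # indiscernibles
  set.seed(202)
  for (k in 1:10) {
    x <- random_seq(200)
    y <- substitute_at(x, sample(200, sample(0:30, 1)))
    expect_gte(p_distance(x, y), 0)
    expect_equal(p_distance(x, y), p_distance(y, x))
  }
})

test_that("single-linkage cluster proxy matches brute-force components", {
  base <- random_seq(500, 111)
  b <- substitute_at(base, 1:10)        # 2% from base
  c_ <- substitute_at(b, 101:110)       # 2% from b, 4% from base
  far <- substitute_at(base, seq(1, 500, by = 10))  # 10% from base
  lib <- reference_library(c("a", "b", "c", "z"), c(base, b, c_, far))
  cl <- cluster_bins(lib)
  # chain a-b-c merges through single linkage although a-c is 4%
  expect_equal(unname(cl[c("a", "b", "c")]), rep("a", 3))
  expect_false(cl[["z"]] == cl[["a"]])

  # random libraries: proxy equals BFS components with identical labels
  set.seed(112)
  for (trial in 1:3) {
    n <- sample(10:20, 1)
    roots <- replicate(3, random_seq(300))
    seqs <- vapply(seq_len(n), function(i) {
      substitute_at(roots[sample(3, 1)], sample(300, sample(0:8, 1)))
    }, character(1))
    ids <- sprintf("s%02d", sample(n))
    lib <- reference_library(ids, seqs)
    got <- cluster_bins(lib)
    want <- components_oracle(seqs, ids, classifier_config()$bin_proxy_threshold)
    expect_equal(unname(got), want)
  }
})

test_that("cluster taxonomy match assigns the lowest conflict-free rank", {
  tax <- data.frame(
    phylum = "Arthropoda", class = "Insecta", order = "Diptera",
    family = "Asilidae", subfamily = "",
    genus = c("Laphria", "Laphria"),
    species = c("Laphria flava", "Laphria flava"))
  members <- cbind(id = c("m1", "m2"), tax, distance = c(0.01, 0.012),
                   stringsAsFactors = FALSE)
  r <- assign_bin_match("q", members)
  expect_equal(r$method, "bin_match")
  expect_equal(r$rank, "species")
  expect_equal(unname(r$taxonomy["species"]), "Laphria flava")

  members2 <- members
  members2$species <- c("Laphria flava", "Laphria gilva")
  r2 <- assign_bin_match("q", members2)
  expect_equal(r2$rank, "genus")
  expect_equal(unname(r2$taxonomy["genus"]), "Laphria")
  expect_equal(unname(r2$taxonomy["species"]), "")

  unidentified <- members
  unidentified[, TAXONOMY_RANKS] <- ""
  expect_null(assign_bin_match("q", unidentified))
})

test_that("nearest-match thresholds are strict and conflict-aware", {
  ref <- random_seq(658, 121)
  make_tax <- function(genus, species) {
    data.frame(phylum = "Arthropoda", class = "Insecta", order = "Diptera",
               family = "Asilidae", subfamily = "", genus = genus,
               species = species, stringsAsFactors = FALSE)
  }
  lib <- reference_library(
    c("r1", "r2"),
    c(ref, substitute_at(ref, seq(1, 658, length.out = 80))),
    taxonomy = rbind(make_tax("Laphria", "Laphria flava"),
                     make_tax("Promachus", "Promachus rufipes")))

  q_species <- seq_at_mismatches(ref, round(0.015 * 658))  # 1.5%
  r <- assign_id_engine(q_species, "q1", lib)
  expect_equal(r$method, "id_engine")
  expect_equal(r$rank, "species")

  q_genus <- seq_at_mismatches(ref, round(0.030 * 658))    # 3.0%
  r2 <- assign_id_engine(q_genus, "q2", lib)
  expect_equal(r2$rank, "genus")

  q_none <- seq_at_mismatches(ref, round(0.060 * 658))     # 6.0%
  r3 <- assign_id_engine(q_none, "q3", lib)
  expect_equal(r3$method, "none")

  # exactly 2.0% divergence: "less than 2%" is strict, so genus at most
  ref5 <- random_seq(500, 122)
  lib_edge <- reference_library(
    c("e1", "e2"),
    c(ref5, substitute_at(ref5, seq(1, 500, length.out = 60))),
    taxonomy = rbind(make_tax("Laphria", "Laphria flava"),
                     make_tax("Promachus", "Promachus rufipes")))
  q_edge <- substitute_at(ref5, round(seq(3, 498, length.out = 10)))
  expect_equal(p_distance(q_edge, ref5), 0.02)
  r4 <- assign_id_engine(q_edge, "q4", lib_edge)
  expect_equal(r4$rank, "genus")

  # best match under 2% but two congeneric species within 2%: genus only
  lib5 <- reference_library(
    c("r1", "r2"),
    c(ref, substitute_at(ref, 1:4)),   # r2 ~0.6% from r1
    taxonomy = rbind(make_tax("Laphria", "Laphria flava"),
                     make_tax("Laphria", "Laphria gilva")))
  q5 <- substitute_at(ref, round(seq(30, 658, length.out = 6)))
  r5 <- assign_id_engine(q5, "q5", lib5)
  expect_lt(r5$best_distance, 0.02)
  expect_equal(r5$rank, "genus")
})

test_that("assigned rank is monotone in distance over random fixtures", {
  set.seed(131)
  ref <- random_seq(658)
  lib <- reference_library(
    "r1", ref,
    taxonomy = data.frame(phylum = "Arthropoda", class = "Insecta",
                          order = "Diptera", family = "Asilidae",
                          subfamily = "", genus = "Laphria",
                          species = "Laphria flava"))
  for (trial in 1:100) {
    k1 <- sample(0:70, 1)
    k2 <- sample(0:70, 1)
    lo <- min(k1, k2); hi <- max(k1, k2)
    r_lo <- assign_id_engine(if (lo) substitute_at(ref, sample(658, lo)) else
      ref, "a", lib)
    r_hi <- assign_id_engine(if (hi) substitute_at(ref, sample(658, hi)) else
      ref, "b", lib)
    expect_gte(rank_depth(r_lo$rank), rank_depth(r_hi$rank))
  }
})

test_that("routes are tried in order and never overlap", {
  bc <- simulate_barcodes(12, n_genera = 4, seed = 141)
  lib <- reference_from_barcodes(bc[1:8, ])
  # query identical to an identified reference: cluster route, species
  # query far from every cluster: nearest-match route
  q_far <- seq_at_mismatches(bc$sequence[1], round(0.03 * 658))
  queries <- data.frame(id = c("same", "far"),
                        sequence = c(bc$sequence[1], q_far),
                        stringsAsFactors = FALSE)
  res <- assign_all(queries, lib)
  expect_equal(res$results[["same"]]$method, "bin_match")
  expect_equal(res$results[["same"]]$rank, "species")
  expect_equal(res$results[["far"]]$method, "id_engine")
  n_assigned <- sum(vapply(res$results, function(r) r$method != "none",
                           logical(1)))
  expect_equal(sum(res$summary), n_assigned)
  tsv <- tempfile(fileext = ".tsv")
  out <- write_assignments(res$results, tsv)
  expect_equal(nrow(out), 2)
})

test_that("reference libraries round-trip through FASTA + taxonomy TSV", {
  bc <- simulate_barcodes(6, seed = 151)
  lib <- reference_from_barcodes(bc)
  fa <- tempfile(fileext = ".fasta")
  tx <- tempfile(fileext = ".tsv")
  write_reference_library(lib, fa, tx)
  back <- read_reference_library(fa, tx)
  expect_equal(back$entries$id, lib$entries$id)
  expect_equal(back$entries$sequence, lib$entries$sequence)
  expect_equal(back$entries$genus, lib$entries$genus)
})
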