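# Shared fixtures. The tag set is deterministic and mildly expensive to
# validate, so it is built once per test run.

.fixture_env <- new.env(parent = emptyenv())

shared_tags <- function() {
  if (is.null(.fixture_env$tags)) .fixture_env$tags <- make_tagset()
  .fixture_env$tags
}

random_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute `k` positions (1-based indices) of `seq` with a different base
substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

# a sequence at exactly `k` mismatches from `seq` (positions spread evenly)
seq_at_mismatches <- function(seq, k) {
  n <- nchar(seq)
  substitute_at(seq, unique(round(seq(1, n, length.out = k))))
}

# build a fully tagged read for one well and amplicon
tagged_read <- function(barcode_seq, amp, tags, well_idx) {
  pair <- tags$well_assignment[well_idx, ]
  paste0(tags$forward_tags[pair[1]], amp$fwd$sequence,
         substr(barcode_seq, amp$start + 1, amp$end),
         revcomp(amp$rev$sequence), revcomp(tags$reverse_tags[pair[2]]))
}

# independent Hamming distance (character-wise, no alignment)
hamming_oracle <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent site-by-site p-distance for equal-length, gap-free pairs
pdist_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  use <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[use] != cb[use]) / sum(use)
}

# brute-force single-linkage components via BFS on the thresholded graph;
# dist_fun defaults to the independent site-by-site counter (fixtures are
# equal-length, substitution-only)
components_oracle <- function(seqs, ids, threshold, dist_fun = pdist_oracle) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- dist_fun(seqs[i], seqs[j]) < threshold
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  # label components like cluster_bins: lexicographically smallest member
  vapply(seq_len(n), function(i) sort(ids[comp == comp[i]])[1], character(1))
}

rank_depth <- function(rank) {
  if (is.na(rank)) return(0L)
  match(rank, c("genus", "species"), nomatch = 0L)
}
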