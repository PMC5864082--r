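# Fixtures are built in code; no binary files.

# A tiny fixed catalog with known TAGs (length 20).
fixed_catalog_df <- function() {
  data.frame(
    strain_id   = c("S1", "S2", "S3"),
    ncrna_name  = c("SUT100", "CUT200", "SNR300"),
    ncrna_class = c("SUT", "CUT", "snoRNA"),
    uptag   = c("ACGTACGTACGTACGTACGT",
                "TTGCATGCATGCATGCATGC",
                "GGGTACCTAGGTACCTAGGA"),
    downtag = c("TTTTACGTACGTACGTACGT",
                "CCGCATGCATGCATGCATGA",
                "AAATACCTAGGTACCTAGGT"),
    stringsAsFactors = FALSE
  )
}

write_catalog_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixed_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c("P1", "P2", "B1", "B2"),
    index6 = c("AAAAAA", "AAAAAT", "AAAATA", "AAATAA"),
    condition = "Clim30",
    stage = c("P", "P", "B", "B"),
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  ))
}

random_acgt <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste0, collapse = "")
}

# Mutate exactly k positions of each sequence (distinct positions,
# guaranteed base change).
mutate_k <- function(seqs, k) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste0(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Independent matcher oracle: exhaustive Hamming comparison through
# Biostrings' C pattern matcher (vcountPattern at fixed length).
oracle_match <- function(tags, catalog) {
  ti <- catalog$tag_index
  subj <- Biostrings::DNAStringSet(tags)
  d0 <- vapply(ti$tag, function(p)
    Biostrings::vcountPattern(p, subj, max.mismatch = 0), integer(length(tags)))
  d1 <- vapply(ti$tag, function(p)
    Biostrings::vcountPattern(p, subj, max.mismatch = 1), integer(length(tags)))
  if (length(tags) == 1) { d0 <- matrix(d0, 1); d1 <- matrix(d1, 1) }
  n0 <- rowSums(d0); n1 <- rowSums(d1)
  outcome <- ifelse(n0 == 1, "hit",
             ifelse(n1 == 1, "hit",
             ifelse(n1 >= 2, "ambiguous", "unmatched")))
  strain <- rep(NA_character_, length(tags))
  mism <- rep(NA_integer_, length(tags))
  ex <- which(n0 == 1)
  strain[ex] <- ti$strain_id[apply(d0[ex, , drop = FALSE], 1, which.max)]
  mism[ex] <- 0L
  near <- which(n0 == 0 & n1 == 1)
  strain[near] <- ti$strain_id[apply(d1[near, , drop = FALSE], 1, which.max)]
  mism[near] <- 1L
  data.frame(outcome = outcome, strain_id = strain, mismatches = mism,
             stringsAsFactors = FALSE)
}

# Brute-force best k-medoid cost by enumerating all medoid subsets.
brute_force_pam_cost <- function(d, k) {
  combos <- combn(nrow(d), k)
  min(apply(combos, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min))))
}

write_fastq <- function(ids, seqs, path = tempfile(fileext = ".fastq")) {
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}
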