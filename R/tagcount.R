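#' @name tagcount
#' @title Barcode counting from multiplexed FASTQ
#'
#' @description
#' Turns multiplexed amplicon FASTQ into a strain-by-sample count matrix.
#' Reads are assigned to samples by exact 6-mer index match, trimmed to the
#' TAG by locating the unique flank occurrence, and a TAG is identified when
#' the trimmed read matches the full length of a catalog TAG with at most
#' one mismatch. UPTAG and DOWNTAG hits are summed per strain.
NULL

#' Read a FASTQ file into a data frame
#'
#' Plain or gzip FASTQ; sequences and full headers only (qualities are not
#' used by the identification rule).
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id` (full header text) and `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) bf_schema_error(paste0("no such file: ", path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e)
      bf_stop(paste0("FASTQ parse error in ", path, ": ",
                     conditionMessage(e)), "barfit_parse_error")
  )
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Assign reads to samples by their 6-mer index
#'
#' The index is taken from the `index=XXXXXX` field of the read header.
#' Matching is exact only: any mismatch, or an N in the index, leaves the
#' read unassigned (a value, not an error), avoiding cross-sample bleed.
#'
#' @param reads data.frame from [read_fastq()].
#' @param sheet a `sample_sheet`.
#' @return character vector of sample ids, `NA` for unassigned.
#' @export
demultiplex <- function(reads, sheet) {
  idx <- sub(".*index=([ACGTN]{6}).*", "\\1", reads$read_id)
  idx[!grepl("index=[ACGTN]{6}", reads$read_id)] <- NA_character_
  sheet$sample_id[match(idx, sheet$index6)]
}

#' Extract the TAG region following a flank sequence
#'
#' Locates the unique exact occurrence of `flank5` in each read and returns
#' the `expected_len` bases that follow. Returns `NA` ("no tag") when the
#' flank is absent, occurs more than once, or fewer than `expected_len`
#' bases follow it.
#'
#' @param sequences character vector of read sequences.
#' @param flank5 the 5' flank to anchor on (non-empty).
#' @param expected_len TAG length to extract.
#' @return character vector of TAGs, `NA` where no TAG was extractable.
#' @export
extract_tag <- function(sequences, flank5, expected_len) {
  if (!nzchar(flank5)) bf_parameter_error("flank5 must be non-empty")
  hits <- gregexpr(flank5, sequences, fixed = TRUE)
  start <- vapply(hits, function(h) {
    if (h[1] == -1L || length(h) > 1L) NA_integer_ else h[1]
  }, integer(1))
  tag_start <- start + nchar(flank5)
  tag <- substr(sequences, tag_start, tag_start + expected_len - 1L)
  tag[is.na(start) | nchar(tag) < expected_len] <- NA_character_
  tag
}

# One-hot encode length-L ACGT strings as an n x 4L 0/1 matrix; positions
# with characters outside ACGT contribute no match at that position.
onehot <- function(seqs, L) {
  n <- length(seqs)
  code <- match(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    c("A", "C", "G", "T")
  )
  m <- matrix(0, nrow = n, ncol = 4L * L)
  pos <- rep(seq_len(L), n)           # position within read
  row <- rep(seq_len(n), each = L)
  ok <- !is.na(code)
  m[cbind(row[ok], (pos[ok] - 1L) * 4L + code[ok])] <- 1
  m
}

match_tags_one_length <- function(tags, cat_tags, cat_strain, cat_which) {
  L <- nchar(cat_tags[1])
  n <- length(tags)
  out <- data.frame(outcome = rep("unmatched", n),
                    strain_id = NA_character_, which = NA_character_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  # exact hits first (hash lookup); uniqueness is guaranteed by the catalog
  ex <- match(tags, cat_tags)
  hit0 <- !is.na(ex)
  out$outcome[hit0] <- "hit"
  out$strain_id[hit0] <- cat_strain[ex[hit0]]
  out$which[hit0] <- cat_which[ex[hit0]]
  out$mismatches[hit0] <- 0L
  rest <- which(!hit0)
  if (length(rest) == 0) return(out)
  # Hamming distance to every catalog TAG via one-hot inner products,
  # deduplicated over unique observed tags and chunked to bound memory.
  uniq <- unique(tags[rest])
  Tm <- onehot(cat_tags, L)
  best_n0 <- integer(length(uniq))   # tags at distance 0 (none, by construction)
  n1  <- integer(length(uniq))       # tags at distance 1
  hit1 <- integer(length(uniq))      # index of the unique distance-1 tag
  chunk <- max(1L, floor(4e6 / length(cat_tags)))
  for (lo in seq(1L, length(uniq), by = chunk)) {
    sel <- lo:min(lo + chunk - 1L, length(uniq))
    Rm <- onehot(uniq[sel], L)
    mism <- L - Rm %*% t(Tm)
    is1 <- mism <= 1 + 1e-9
    cnt <- rowSums(is1)
    n1[sel] <- cnt
    w <- which(cnt == 1)
    if (length(w) > 0)
      hit1[sel[w]] <- apply(is1[w, , drop = FALSE], 1, which.max)
  }
  res_outcome <- ifelse(n1 == 0, "unmatched",
                 ifelse(n1 == 1, "hit", "ambiguous"))
  mu <- match(tags[rest], uniq)
  out$outcome[rest] <- res_outcome[mu]
  oh <- rest[res_outcome[mu] == "hit"]
  ti <- hit1[mu[res_outcome[mu] == "hit"]]
  out$strain_id[oh] <- cat_strain[ti]
  out$which[oh] <- cat_which[ti]
  out$mismatches[oh] <- 1L
  out
}

#' Identify TAGs against the catalog by full-length Hamming match
#'
#' A TAG is identified if it matches the full length of a catalog TAG with
#' at most one mismatch: distance 0 is a hit; exactly one catalog TAG at
#' distance 1 (and none at 0) is a hit with one mismatch; two or more
#' catalog TAGs at the minimum distance <= 1 is ambiguous; anything else is
#' unmatched. Only catalog TAGs of the same length as the query are
#' considered.
#'
#' @param tags character vector of extracted TAG sequences (`NA` allowed:
#'   reported as `no_tag`).
#' @param catalog a `barcode_catalog`.
#' @return data.frame with `outcome` (`hit`/`ambiguous`/`unmatched`/
#'   `no_tag`), `strain_id`, `which`, `mismatches`.
#' @export
match_tag <- function(tags, catalog) {
  ti <- catalog$tag_index
  n <- length(tags)
  out <- data.frame(outcome = rep("no_tag", n), strain_id = NA_character_,
                    which = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  ok <- which(!is.na(tags) & nzchar(tags))
  if (length(ok) == 0 || nrow(ti) == 0) {
    out$outcome[ok] <- "unmatched"
    return(out)
  }
  cat_len <- nchar(ti$tag)
  for (L in unique(nchar(tags[ok]))) {
    q <- ok[nchar(tags[ok]) == L]
    sel <- cat_len == L
    if (!any(sel)) {
      out$outcome[q] <- "unmatched"
      next
    }
    r <- match_tags_one_length(tags[q], ti$tag[sel], ti$strain_id[sel],
                               ti$which[sel])
    out[q, ] <- r
  }
  out
}

#' Count a sequencing run into a strain-by-sample matrix
#'
#' For each sample, the strain count is the sum of its UPTAG and DOWNTAG
#' hits. Per-sample accounting tallies (hits, ambiguous, unmatched, no_tag)
#' always sum to the reads processed for that sample; reads whose index
#' matches no sample are tallied separately as unassigned.
#'
#' @param up_fastq,down_fastq paths to the UPTAG and DOWNTAG run FASTQ
#'   files (vectors allowed; files of a run are concatenated).
#' @param catalog a `barcode_catalog`.
#' @param sheet a `sample_sheet`.
#' @param revcomp also scan the reverse complement of reads whose forward
#'   orientation yields no TAG (off by default; simulated reads have a
#'   fixed orientation).
#' @return list of class `barseq_counts`: `counts` (integer matrix strains
#'   x samples), `accounting` (per-sample tallies), `unassigned` (reads
#'   with unknown index).
#' @export
count_run <- function(up_fastq, down_fastq, catalog, sheet,
                      revcomp = FALSE) {
  strains <- catalog$records$strain_id
  counts <- matrix(0L, nrow = length(strains), ncol = nrow(sheet),
                   dimnames = list(strains, sheet$sample_id))
  acct <- data.frame(sample_id = sheet$sample_id, reads = 0L, hits = 0L,
                     ambiguous = 0L, unmatched = 0L, no_tag = 0L,
                     stringsAsFactors = FALSE)
  unassigned <- 0L
  tag_lens <- unique(nchar(catalog$tag_index$tag))
  for (which in c("up", "down")) {
    paths <- if (which == "up") up_fastq else down_fastq
    fl <- tag_flanks(which)
    for (path in paths) {
      reads <- read_fastq(path)
      if (nrow(reads) == 0) next
      sample_of <- demultiplex(reads, sheet)
      unassigned <- unassigned + sum(is.na(sample_of))
      keep <- which(!is.na(sample_of))
      if (length(keep) == 0) next
      seqs <- reads$sequence[keep]
      res <- match_best_length(seqs, fl$flank5, tag_lens, catalog)
      if (revcomp) {
        miss <- res$outcome == "no_tag"
        if (any(miss)) {
          rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(seqs[miss])))
          res[miss, ] <- match_best_length(rc, fl$flank5, tag_lens, catalog)
        }
      }
      sm <- sample_of[keep]
      for (cat_col in split(seq_along(sm), sm)) {
        j <- match(sm[cat_col[1]], sheet$sample_id)
        r <- res[cat_col, , drop = FALSE]
        acct$reads[j]     <- acct$reads[j] + nrow(r)
        acct$hits[j]      <- acct$hits[j] + sum(r$outcome == "hit")
        acct$ambiguous[j] <- acct$ambiguous[j] + sum(r$outcome == "ambiguous")
        acct$unmatched[j] <- acct$unmatched[j] + sum(r$outcome == "unmatched")
        acct$no_tag[j]    <- acct$no_tag[j] + sum(r$outcome == "no_tag")
        hit <- r$strain_id[r$outcome == "hit"]
        if (length(hit) > 0) {
          tab <- table(hit)
          counts[names(tab), j] <- counts[names(tab), j] + as.integer(tab)
        }
      }
    }
  }
  structure(list(counts = counts, accounting = acct,
                 unassigned = unassigned),
            class = "barseq_counts")
}

# Extract at each candidate TAG length and keep, per read, the best match:
# fewest mismatches wins; equal best at different lengths -> ambiguous.
match_best_length <- function(seqs, flank5, tag_lens, catalog) {
  res <- NULL
  for (L in sort(tag_lens)) {
    tags <- extract_tag(seqs, flank5, L)
    r <- match_tag(tags, catalog)
    if (is.null(res)) { res <- r; next }
    better <- (r$outcome == "hit" & res$outcome != "hit") |
      (r$outcome == "hit" & res$outcome == "hit" &
         r$mismatches < res$mismatches)
    tie <- r$outcome == "hit" & res$outcome == "hit" &
      r$mismatches == res$mismatches & r$strain_id != res$strain_id
    amb <- r$outcome == "ambiguous" & res$outcome != "hit"
    res[better, ] <- r[better, ]
    res$outcome[tie] <- "ambiguous"
    res$strain_id[tie] <- NA_character_
    res$which[tie] <- NA_character_
    res$mismatches[tie] <- NA_integer_
    res$outcome[amb] <- "ambiguous"
  }
  res
}

#' @export
print.barseq_counts <- function(x, ...) {
  cat("barseq_counts:", nrow(x$counts), "strains x", ncol(x$counts),
      "samples;", sum(x$accounting$reads), "assigned reads (",
      x$unassigned, "unassigned )\n")
  invisible(x)
}

#' Write a count matrix and its accounting table to TSV
#'
#' @param bc a `barseq_counts`.
#' @param counts_path,accounting_path output paths.
#' @export
write_counts <- function(bc, counts_path, accounting_path = NULL) {
  df <- data.frame(strain_id = rownames(bc$counts), bc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(accounting_path))
    write.table(bc$accounting, accounting_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(counts_path)
}
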