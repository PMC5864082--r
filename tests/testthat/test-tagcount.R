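test_that("demultiplexing is exact-match only", {
  sheet <- fixed_sheet()
  reads <- data.frame(
    read_id = c("r1 index=AAAAAA", "r2 index=AAAAAT", "r3 index=CAAAAA",
                "r4 index=AANAAA", "r5"),
    sequence = "ACGT", stringsAsFactors = FALSE)
  got <- demultiplex(reads, sheet)
  expect_equal(got, c("P1", "P2", NA, NA, NA))
})

test_that("TAG extraction anchors on a unique flank occurrence", {
  fl <- "GATGTCCACGAGGTCTCT"
  tag <- "ACGTACGTACGTACGTACGT"
  expect_equal(extract_tag(paste0(fl, tag, "CGTACG"), fl, 20L), tag)
  # flank absent
  expect_true(is.na(extract_tag("ACGTACGTACGT", fl, 20L)))
  # too few bases after the flank
  expect_true(is.na(extract_tag(paste0(fl, "ACGT"), fl, 20L)))
  # flank occurring twice (the TAG region itself contains the flank):
  # a brute-force substring scan confirms two occurrences
  read2 <- paste0(fl, fl, "AC", "CGTACG")
  occ <- length(gregexpr(fl, read2, fixed = TRUE)[[1]])
  expect_equal(occ, 2)
  expect_true(is.na(extract_tag(read2, fl, 20L)))
  expect_error(extract_tag("ACGT", "", 20L), class = "barfit_parameter_error")
})

test_that("TAG matching applies the full-length <=1 mismatch rule", {
  cat <- as_barcode_catalog(fixed_catalog_df())
  up1 <- fixed_catalog_df()$uptag[1]
  # identity
  m <- match_tag(up1, cat)
  expect_equal(m$outcome, "hit")
  expect_equal(m$strain_id, "S1")
  expect_equal(m$which, "up")
  expect_equal(m$mismatches, 0L)
  # one mismatch from exactly one TAG
  mut <- paste0("C", substring(up1, 2))
  m <- match_tag(mut, cat)
  expect_equal(m$outcome, "hit")
  expect_equal(m$mismatches, 1L)
  expect_equal(m$strain_id, "S1")
  # two mismatches -> unmatched
  mut2 <- paste0("CA", substring(up1, 3))
  expect_equal(match_tag(mut2, cat)$outcome, "unmatched")
  # equidistant from two TAGs -> ambiguous (S1 up and down differ at 4 sites)
  amb_cat <- as_barcode_catalog(data.frame(
    strain_id = c("A", "B"), ncrna_name = c("SUT1", "SUT2"),
    ncrna_class = "SUT",
    uptag   = c("AACGTACGTACGTACGTACG", "CACGTACGTACGTACGTACG"),
    downtag = c("GGCGTACGTACGTACGTACG", "TTCGTACGTACGTACGTACG"),
    stringsAsFactors = FALSE))
  # query differs from A's uptag and B's uptag by one base each
  q <- "TACGTACGTACGTACGTACG"
  expect_equal(match_tag(q, amb_cat)$outcome, "ambiguous")
  # NA input is reported as no_tag
  expect_equal(match_tag(NA_character_, cat)$outcome, "no_tag")
  # length with no catalog TAGs -> unmatched
  expect_equal(match_tag("ACGTACGTACGTACG", cat)$outcome, "unmatched")
})

test_that("the matcher agrees with an exhaustive Hamming oracle", {
  set.seed(71)
  cfg <- sim_config(n_strains = 100L, seed = 71L)
  catalog <- simulate_catalog(cfg)
  base <- catalog$tag_index$tag
  tags <- c(sample(base, 300, replace = TRUE),
            mutate_k(sample(base, 300, replace = TRUE), 1),
            mutate_k(sample(base, 300, replace = TRUE), 2),
            random_acgt(300, 20))
  mine <- match_tag(tags, catalog)
  orac <- oracle_match(tags, catalog)
  expect_equal(mine$outcome, orac$outcome)
  expect_equal(mine$strain_id, orac$strain_id)
  expect_equal(mine$mismatches, orac$mismatches)
})

test_that("counts sum UPTAG and DOWNTAG hits per strain", {
  df <- fixed_catalog_df()
  cat <- as_barcode_catalog(df)
  sheet <- fixed_sheet()
  fl_up <- tag_flanks("up"); fl_down <- tag_flanks("down")
  up_reads <- paste0(fl_up$flank5, rep(df$uptag[1], 100), fl_up$flank3)
  down_reads <- paste0(fl_down$flank5, rep(df$downtag[1], 50),
                       fl_down$flank3)
  up_fq <- write_fastq(paste0("u", 1:100, " index=AAAAAA"), up_reads)
  down_fq <- write_fastq(paste0("d", 1:50, " index=AAAAAA"), down_reads)
  bc <- count_run(up_fq, down_fq, cat, sheet)
  expect_equal(unname(bc$counts["S1", "P1"]), 150L)
  expect_equal(sum(bc$counts), 150L)
  acct <- bc$accounting
  expect_true(all(acct$reads ==
    acct$hits + acct$ambiguous + acct$unmatched + acct$no_tag))
})

test_that("an empty FASTQ yields all-zero counts with zero tallies", {
  cat <- as_barcode_catalog(fixed_catalog_df())
  sheet <- fixed_sheet()
  empty <- tempfile(fileext = ".fastq"); file.create(empty)
  bc <- count_run(empty, empty, cat, sheet)
  expect_true(all(bc$counts == 0))
  expect_true(all(bc$accounting$reads == 0))
})

test_that("counting a simulated error-free run recovers the multinomial draw", {
  cfg <- sim_config(n_strains = 30L, depth = 2000, error_rate = 0, seed = 6L)
  catalog <- simulate_catalog(cfg)
  sheet <- as_sample_sheet(data.frame(
    sample_id = "x", index6 = "GATTAC", condition = "Nlim30",
    stage = "P", replicate = 1L))
  pool <- simulate_pool(cfg, "Nlim30", 1L)
  eu <- emit_reads(pool$states$P, catalog, "GATTAC", cfg, "up", seed = 21L)
  ed <- emit_reads(pool$states$P, catalog, "GATTAC", cfg, "down", seed = 22L)
  up_fq <- tempfile(fileext = ".fastq"); writeLines(eu$fastq, up_fq)
  down_fq <- tempfile(fileext = ".fastq"); writeLines(ed$fastq, down_fq)
  bc <- count_run(up_fq, down_fq, catalog, sheet)
  want <- eu$draw + ed$draw
  expect_equal(bc$counts[names(want), "x"], want)
  expect_equal(bc$accounting$hits, 4000L)
})

test_that("raising the error rate never raises the hit fraction", {
  hit_frac <- function(e) {
    cfg <- sim_config(n_strains = 40L, depth = 3000, error_rate = e,
                      seed = 13L)
    catalog <- simulate_catalog(cfg)
    pool <- simulate_pool(cfg, "Clim30", 1L)
    er <- emit_reads(pool$states$B, catalog, "AAAAAA", cfg, "up", seed = 31L)
    seqs <- er$fastq[seq(2, length(er$fastq), 4)]
    tags <- extract_tag(seqs, tag_flanks("up")$flank5, 20L)
    mean(match_tag(tags, catalog)$outcome == "hit")
  }
  expect_gte(hit_frac(0), hit_frac(0.02))
  expect_equal(hit_frac(0), 1.0)
})

test_that("reverse-complement scanning rescues flipped reads when enabled", {
  df <- fixed_catalog_df()
  cat <- as_barcode_catalog(df)
  sheet <- fixed_sheet()
  fl <- tag_flanks("up")
  fwd <- paste0(fl$flank5, df$uptag[2], fl$flank3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  fq <- write_fastq("r1 index=AAAAAA", rc)
  empty <- tempfile(fileext = ".fastq"); file.create(empty)
  bc_plain <- count_run(fq, empty, cat, sheet)
  expect_equal(sum(bc_plain$counts), 0L)
  bc_rc <- count_run(fq, empty, cat, sheet, revcomp = TRUE)
  expect_equal(unname(bc_rc$counts["S2", "P1"]), 1L)
})
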