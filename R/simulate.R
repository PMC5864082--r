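#' @name simulate
#' @title Ground-truthed simulation of the competitive fitness experiment
#'
#' @description
#' The generator emulates the study design end to end: a pool of barcoded
#' heterozygous deletion strains grown through batch culture into chemostat
#' steady state under a per-strain selection coefficient, sampled at the
#' pool (P), batch (B) and early/mid/late steady-state stages, sequenced as
#' multiplexed UPTAG and DOWNTAG amplicon reads with substitution errors;
#' plus arrayed colony plates with a majority normal-growth class and a
#' reduced-fitness class, and logistic monoculture growth curves.
NULL

# Amplicon layout: each read is flank5 + TAG + flank3 where the flanks are
# the 3' ends of the amplification primers (the 5' flank read directly, the
# 3' flank as the reverse complement of the reverse primer's 3' end).
UPTAG_FLANK5   <- "GATGTCCACGAGGTCTCT"
UPTAG_FLANK3   <- "CGTACGCTGCAGGTCGAC"
DOWNTAG_FLANK5 <- "CGAGCTCGAATTCATCGAT"
DOWNTAG_FLANK3 <- "CTACGAGACCGACACCG"

#' Flank sequences for a TAG amplicon run
#' @param which `"up"` or `"down"`.
#' @return list with `flank5` and `flank3` character strings.
#' @export
tag_flanks <- function(which = c("up", "down")) {
  which <- match.arg(which)
  if (which == "up") list(flank5 = UPTAG_FLANK5, flank3 = UPTAG_FLANK3)
  else list(flank5 = DOWNTAG_FLANK5, flank3 = DOWNTAG_FLANK3)
}

#' Simulation configuration
#'
#' Defaults are the study conditions: 6 batch generations (24 h of batch
#' growth), 7 generations to settle into steady state, samples at early
#' steady state then 20 and 30 steady-state generations (MSS, LSS), two
#' biological repeats, and per-repeat effect jitter so that repeats are
#' non-identical.
#'
#' @param n_strains number of strains in the pool.
#' @param g_batch generations from pool to batch sample.
#' @param g_settle generations from batch to early steady state.
#' @param g_ss steady-state generations from ESS to LSS (MSS is taken at 20).
#' @param depth reads per sample per TAG run.
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param fraction_null,fraction_hi,fraction_hp mixture of strain classes;
#'   must sum to 1.
#' @param effect_size magnitude `|s|` of the per-generation log2 growth-rate
#'   offset for non-null strains.
#' @param rep_jitter_sd sd of the per-repeat jitter added to `s`.
#' @param n_bio_reps biological repeats per condition.
#' @param tag_len length of simulated TAG sequences.
#' @param seed master seed; all stage randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 500L, g_batch = 6, g_settle = 7,
                       g_ss = 30, depth = 1e5, error_rate = 0.01,
                       fraction_null = 0.9, fraction_hi = 0.05,
                       fraction_hp = 0.05, effect_size = 0.2,
                       rep_jitter_sd = 0.02, n_bio_reps = 2L,
                       tag_len = 20L, seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains), g_batch = g_batch,
              g_settle = g_settle, g_ss = g_ss, depth = depth,
              error_rate = error_rate, fraction_null = fraction_null,
              fraction_hi = fraction_hi, fraction_hp = fraction_hp,
              effect_size = effect_size, rep_jitter_sd = rep_jitter_sd,
              n_bio_reps = as.integer(n_bio_reps),
              tag_len = as.integer(tag_len), seed = as.integer(seed))
  if (abs(cfg$fraction_null + cfg$fraction_hi + cfg$fraction_hp - 1) > 1e-12)
    bf_parameter_error("class fractions must sum to 1")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.1)
    bf_parameter_error("error_rate must be in [0, 0.1)")
  if (cfg$depth < 1) bf_parameter_error("depth must be >= 1")
  if (any(c(cfg$g_batch, cfg$g_settle, cfg$g_ss) < 0))
    bf_parameter_error("generation counts must be >= 0")
  if (cfg$n_strains < 1) bf_parameter_error("n_strains must be >= 1")
  if (cfg$tag_len < MIN_TAG_LEN)
    bf_parameter_error(paste0("tag_len must be >= ", MIN_TAG_LEN))
  structure(cfg, class = "sim_config")
}

random_tags <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Simulate a barcode catalog with unique TAGs
#'
#' @param config a [sim_config()].
#' @return a `barcode_catalog` with strains `S0001`... carrying random
#'   unique TAGs and ncRNA names drawn across the catalogued classes.
#' @export
simulate_catalog <- function(config) {
  set.seed(substream_seed(config$seed, "catalog"))
  n <- config$n_strains
  tags <- unique(random_tags(2L * n + 50L, config$tag_len))
  while (length(tags) < 2L * n)
    tags <- unique(c(tags, random_tags(2L * n, config$tag_len)))
  cls_pool <- c("SUT", "CUT", "tRNA", "snoRNA", "other")
  cls <- sample(cls_pool, n, replace = TRUE,
                prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
  name <- paste0(ifelse(cls == "tRNA", "tA(UGC)",
                 ifelse(cls == "snoRNA", "SNR",
                 ifelse(cls == "other", "NCR", cls))), seq_len(n))
  df <- data.frame(
    strain_id   = sprintf("S%04d", seq_len(n)),
    ncrna_name  = name,
    ncrna_class = cls,
    uptag       = tags[seq_len(n)],
    downtag     = tags[n + seq_len(n)],
    stringsAsFactors = FALSE
  )
  as_barcode_catalog(df)
}

#' Draw the per-strain fitness truth for one condition
#'
#' Strains are null (s = 0), haplo-insufficient (s = -effect_size) or
#' haplo-proficient (s = +effect_size) in the configured proportions.
#'
#' @param config a [sim_config()].
#' @param condition condition label (selects the substream).
#' @return data.frame `strain_id`, `class` (HI/HP/null), `s`.
#' @export
simulate_truth <- function(config, condition = "Clim30") {
  set.seed(substream_seed(config$seed, paste0("truth:", condition)))
  n <- config$n_strains
  cls <- sample(c("null", "HI", "HP"), n, replace = TRUE,
                prob = c(config$fraction_null, config$fraction_hi,
                         config$fraction_hp))
  s <- ifelse(cls == "HI", -config$effect_size,
       ifelse(cls == "HP", config$effect_size, 0))
  data.frame(strain_id = sprintf("S%04d", seq_len(n)), class = cls, s = s,
             stringsAsFactors = FALSE)
}

grow <- function(f, s, g) {
  # g generations of f_i <- f_i 2^(1+s_i) / sum_j f_j 2^(1+s_j); the shared
  # 2^1 cancels, so the closed form is a renormalised power of 2^s.
  if (g == 0) return(f)
  w <- f * 2^(g * s)
  w / sum(w)
}

#' Simulate a competitive pool trajectory through the sampling stages
#'
#' Relative strain abundances evolve by per-generation replicator dynamics
#' under selection coefficients `s` (log2 growth-rate offset per
#' generation). States are emitted at pool (P), batch (B, after `g_batch`
#' generations), early steady state (ESS, after `g_settle` more), mid steady
#' state (MSS, 20 steady-state generations after ESS) and late steady state
#' (LSS, `g_ss` generations after ESS).
#'
#' @param config a [sim_config()].
#' @param condition condition label.
#' @param replicate biological repeat number; each repeat applies its own
#'   jitter `s' = s + N(0, rep_jitter_sd)` from the batch phase on, so
#'   repeats are non-identical.
#' @param truth optional data.frame from [simulate_truth()]; drawn if NULL.
#' @return list with `states` (named list stage -> abundance vector summing
#'   to 1) and `truth`.
#' @export
simulate_pool <- function(config, condition = "Clim30", replicate = 1L,
                          truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config, condition)
  n <- config$n_strains
  set.seed(substream_seed(config$seed,
                          paste0("jitter:", condition, ":", replicate)))
  s_rep <- truth$s + rnorm(n, 0, config$rep_jitter_sd)
  f0 <- rep(1 / n, n)
  fB   <- grow(f0, s_rep, config$g_batch)
  fE   <- grow(fB, s_rep, config$g_settle)
  fM   <- grow(fE, s_rep, 20)
  fL   <- grow(fE, s_rep, config$g_ss)
  states <- list(P = f0, B = fB, ESS = fE, MSS = fM, LSS = fL)
  states <- lapply(states, function(f) setNames(f, truth$strain_id))
  list(states = states, truth = truth)
}

mutate_reads <- function(seqs, e, alphabet = c("A", "C", "G", "T")) {
  if (e == 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  hit <- which(runif(length(m)) < e)
  if (length(hit) > 0) {
    # substitute with one of the three other bases, uniformly
    cur <- m[hit]
    sub <- vapply(cur, function(b) sample(setdiff(alphabet, b), 1L), "")
    m[hit] <- sub
  }
  apply(m, 1, paste0, collapse = "")
}

#' Emit multiplexed amplicon reads for one sample
#'
#' Draws `depth` reads per TAG run multinomially over strain abundances,
#' builds each read as `flank5 + TAG + flank3`, applies independent per-base
#' substitution errors, and records the 6-mer sample index in the FASTQ
#' header (`index=XXXXXX`), mimicking demultiplex-ready data. Read ids
#' encode the true strain for debugging. Qualities are constant `I`.
#'
#' @param abund named abundance vector (a stage from [simulate_pool()]).
#' @param catalog a `barcode_catalog` covering all strains in `abund`.
#' @param index6 the sample's 6-mer index.
#' @param config a [sim_config()].
#' @param which `"up"` or `"down"` TAG run.
#' @param seed integer seed for this sample's draws.
#' @return list with `fastq` (character vector of 4-line records, one
#'   element per line) and `draw` (named integer vector: the true
#'   multinomial read counts per strain).
#' @export
emit_reads <- function(abund, catalog, index6, config,
                       which = c("up", "down"), seed = 1L) {
  which <- match.arg(which)
  if (abs(sum(abund) - 1) > 1e-9 || any(abund < 0))
    bf_parameter_error("abundances must be non-negative and sum to 1")
  recs <- catalog$records
  if (!all(names(abund) %in% recs$strain_id))
    bf_parameter_error("catalog does not cover all simulated strains")
  set.seed(seed)
  draw <- as.integer(rmultinom(1, size = config$depth, prob = abund))
  names(draw) <- names(abund)
  fl <- tag_flanks(which)
  tag <- recs[[if (which == "up") "uptag" else "downtag"]][
    match(names(abund), recs$strain_id)]
  strain_of_read <- rep(names(abund), draw)
  seqs <- paste0(fl$flank5, rep(tag, draw), fl$flank3)
  seqs <- mutate_reads(seqs, config$error_rate)
  ids <- paste0("@sim:", which, ":", strain_of_read, ":",
                seq_along(seqs), " index=", index6)
  qual <- strrep("I", nchar(seqs))
  fastq <- as.vector(rbind(ids, seqs, "+", qual))
  list(fastq = fastq, draw = draw)
}

#' Simulate strain-by-sample barcode counts directly
#'
#' The error-free shortcut through read emission: for each sample the
#' summed UPTAG + DOWNTAG count of a strain is the sum of two independent
#' multinomial draws of `depth` reads over the stage abundances -- exactly
#' what [count_run()] recovers from [emit_reads()] output at
#' `error_rate = 0`. Used for statistical calibration at depths where
#' emitting literal reads is pointless.
#'
#' @param config a [sim_config()].
#' @param sheet a `sample_sheet`; one column is generated per row.
#' @param condition condition to simulate (sheet rows are filtered to it).
#' @param truth optional truth table shared across replicates.
#' @return list with `counts` (integer matrix strains x samples), `truth`,
#'   and `pools` (per-replicate [simulate_pool()] output).
#' @export
simulate_counts <- function(config, sheet, condition = "Clim30",
                            truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config, condition)
  rows <- sheet[sheet$condition == condition, , drop = FALSE]
  if (nrow(rows) == 0) bf_parameter_error("no sheet rows for condition")
  pools <- lapply(unique(rows$replicate), function(r)
    simulate_pool(config, condition, r, truth))
  names(pools) <- as.character(unique(rows$replicate))
  counts <- matrix(0L, nrow = config$n_strains, ncol = nrow(rows),
                   dimnames = list(truth$strain_id, rows$sample_id))
  for (i in seq_len(nrow(rows))) {
    f <- pools[[as.character(rows$replicate[i])]]$states[[rows$stage[i]]]
    set.seed(substream_seed(config$seed,
      paste0("counts:", rows$sample_id[i])))
    up   <- rmultinom(1, size = config$depth, prob = f)
    down <- rmultinom(1, size = config$depth, prob = f)
    counts[, i] <- as.integer(up + down)
  }
  list(counts = counts, truth = truth, pools = pools)
}

#' Simulate arrayed colony plates with ground truth
#'
#' Colony size = plate scale x class mean x lognormal noise. A fraction of
#' strains belongs to a reduced-fitness class; wild-type control positions
#' are marked and always draw from the normal class.
#'
#' @param strain_ids strains to array (each placed `n_tech` times).
#' @param n_tech technical replicate positions per strain.
#' @param nrow_grid,ncol_grid plate grid dimensions (384-format default).
#' @param fraction_reduced fraction of strains in the reduced class.
#' @param mean_normal,mean_reduced class means of normalized colony size.
#' @param noise_sd sdlog of the per-colony lognormal noise.
#' @param plate_effect_sd sdlog of the per-plate scale factor.
#' @param n_wt wild-type control positions per plate.
#' @param seed integer seed.
#' @return list with `plates` (data.frame plate_id,row,col,strain_id,size,
#'   is_wt) and `truth` (strain_id, class, class_mean).
#' @export
simulate_plates <- function(strain_ids, n_tech = 4L, nrow_grid = 16L,
                            ncol_grid = 24L, fraction_reduced = 0.1,
                            mean_normal = 1, mean_reduced = 0.6,
                            noise_sd = 0.05, plate_effect_sd = 0.1,
                            n_wt = 16L, seed = 1L) {
  if (nrow_grid < 2 || ncol_grid < 2)
    bf_parameter_error("plate grid must be at least 2x2")
  set.seed(seed)
  n <- length(strain_ids)
  cls <- ifelse(runif(n) < fraction_reduced, "reduced", "normal")
  mu  <- ifelse(cls == "reduced", mean_reduced, mean_normal)
  truth <- data.frame(strain_id = strain_ids, class = cls, class_mean = mu,
                      stringsAsFactors = FALSE)
  per_plate <- nrow_grid * ncol_grid - n_wt
  entries <- data.frame(
    strain_id = rep(strain_ids, each = n_tech),
    class_mean = rep(mu, each = n_tech),
    is_wt = FALSE, stringsAsFactors = FALSE
  )
  n_plates <- ceiling(nrow(entries) / per_plate)
  out <- vector("list", n_plates)
  idx <- seq_len(nrow(entries))
  for (p in seq_len(n_plates)) {
    take <- idx[idx > (p - 1) * per_plate & idx <= p * per_plate]
    e <- entries[take, , drop = FALSE]
    wt <- data.frame(strain_id = "WT", class_mean = mean_normal,
                     is_wt = TRUE, stringsAsFactors = FALSE)
    e <- rbind(e, wt[rep(1, n_wt), ])
    pos <- seq_len(nrow_grid * ncol_grid)[seq_len(nrow(e))]
    pos <- sample(pos)  # scatter strains and controls over the grid
    plate_scale <- rlnorm(1, 0, plate_effect_sd)
    size <- plate_scale * e$class_mean *
      rlnorm(nrow(e), 0, noise_sd)
    out[[p]] <- data.frame(
      plate_id = sprintf("plate%02d", p),
      row = (pos - 1) %/% ncol_grid + 1L,
      col = (pos - 1) %% ncol_grid + 1L,
      strain_id = e$strain_id, size = size, is_wt = e$is_wt,
      stringsAsFactors = FALSE
    )
  }
  list(plates = do.call(rbind, out), truth = truth)
}

#' Simulate a logistic monoculture growth curve
#'
#' `OD(t) = K / (1 + exp(-r (t - t_mid))) + N(0, noise_sd)`.
#'
#' @param times sampling times in hours, strictly increasing.
#' @param K carrying capacity (OD units).
#' @param r growth rate (1/h).
#' @param t_mid inflection time (h).
#' @param noise_sd sd of additive measurement noise.
#' @param seed integer seed.
#' @return data.frame of class `growth_curve` with `time`, `od`.
#' @export
simulate_growth_curve <- function(times, K = 1, r = 1, t_mid = 5,
                                  noise_sd = 0, seed = 1L) {
  if (length(times) < 2 || any(diff(times) <= 0))
    bf_parameter_error("times must be >= 2 strictly increasing values")
  set.seed(seed)
  od <- K / (1 + exp(-r * (times - t_mid))) + rnorm(length(times), 0, noise_sd)
  structure(data.frame(time = times, od = od),
            class = c("growth_curve", "data.frame"))
}
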