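#' @name pipeline
#' @title One-config orchestration of the whole analysis
#'
#' @description
#' Runs catalog/sheet generation (or loading), read simulation, barcode
#' counting, stage contrasts with HP/HI classification, optional co-fitness
#' clustering and the colony screen from a single YAML (or list) config.
#' All randomness flows from one master seed through named substreams, so
#' a rerun with the same config produces byte-identical artifacts.
NULL

default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_strains = 200L, depth = 20000, error_rate = 0.01,
                    conditions = list("Clim30")),
    thresholds = list(alpha_sig = 0.05, fold = 1.5),
    contrasts = list(list(from = "P", to = "B"),
                     list(from = "ESS", to = "LSS")),
    screen = list(enabled = TRUE, fraction_reduced = 0.1,
                  mean_reduced = 0.6, noise_sd = 0.05,
                  plate_effect_sd = 0.1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config a YAML path or a named list; missing entries fall back to
#'   package defaults.
#' @return validated config list with attribute `hash`.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) bf_schema_error(paste0("no such file: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  th <- cfg$thresholds
  if (th$alpha_sig <= 0 || th$alpha_sig >= 1)
    bf_parameter_error("alpha_sig must be in (0, 1)")
  if (th$fold <= 1)
    bf_parameter_error("fold threshold must exceed 1")
  for (p in c("catalog", "sheet", "fastq_dir", "plates")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]))
      bf_parameter_error(paste0("configured path does not exist: ",
                                cfg$paths[[p]]))
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  h <- 2166136261
  for (k in utf8ToInt(paste(deparse(cfg), collapse = ""))) {
    h <- bitwXor(as.integer(h %% 2147483647), k)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_artifact <- function(df, path, hash) {
  con <- file(path, open = "wb")   # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(paste0("# barfit config=", hash), con)
  lines <- c(paste(colnames(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    bf_stop(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), "barfit_stage_error"))
}

#' Execute the configured pipeline
#'
#' Stages: build catalog and sample sheet, simulate amplicon reads per
#' sample, count barcodes, contrast growth stages and classify HP/HI per
#' condition, screen colony plates. Artifacts are written under `out_dir`
#' with a header naming the config hash; a structured run report with
#' per-stage record counts is written as `report.json` and returned.
#'
#' @param config YAML path or list (see [load_run_config()]).
#' @param out_dir output directory (created if absent).
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- load_run_config(config)
  hash <- attr(cfg, "hash")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "fastq"), showWarnings = FALSE)
  report <- list(version = as.character(utils::packageVersion("barfit")),
                 config_hash = hash, config = cfg, stages = list())
  log_stage <- function(name, ...) {
    counts <- list(...)
    report$stages[[name]] <<- counts
    message("[barfit] ", name, ": ",
            paste(names(counts), unlist(counts), sep = "=", collapse = " "))
  }

  sim <- run_stage("simulate", {
    sc <- sim_config(n_strains = cfg$simulate$n_strains,
                     depth = cfg$simulate$depth,
                     error_rate = cfg$simulate$error_rate,
                     seed = cfg$seed)
    catalog <- simulate_catalog(sc)
    conds <- unlist(cfg$simulate$conditions)
    stages_used <- unique(unlist(lapply(cfg$contrasts,
                                        function(ct) c(ct$from, ct$to))))
    sheet <- expand.grid(stage = stages_used, replicate = 1:2,
                         condition = conds, stringsAsFactors = FALSE)
    sheet <- data.frame(
      sample_id = paste(sheet$condition, sheet$stage, sheet$replicate,
                        sep = "_"),
      index6 = random_index6(nrow(sheet), sc$seed),
      condition = sheet$condition, stage = sheet$stage,
      replicate = sheet$replicate, stringsAsFactors = FALSE)
    sheet <- as_sample_sheet(sheet)
    write_artifact(catalog$records, file.path(out_dir, "catalog.tsv"), hash)
    write_artifact(sheet, file.path(out_dir, "sample_sheet.tsv"), hash)
    truths <- list()
    for (cond in conds) {
      truths[[cond]] <- simulate_truth(sc, cond)
      write_artifact(truths[[cond]],
                     file.path(out_dir, paste0("truth_", cond, ".tsv")), hash)
    }
    up_paths <- character(0); down_paths <- character(0)
    for (cond in conds) {
      pools <- lapply(1:2, function(r)
        simulate_pool(sc, cond, r, truths[[cond]]))
      for (i in which(sheet$condition == cond)) {
        f <- pools[[sheet$replicate[i]]]$states[[sheet$stage[i]]]
        for (w in c("up", "down")) {
          er <- emit_reads(f, catalog, sheet$index6[i], sc, which = w,
                           seed = substream_seed(sc$seed,
                             paste0("reads:", sheet$sample_id[i], ":", w)))
          path <- file.path(out_dir, "fastq",
                            paste0(sheet$sample_id[i], "_", w, ".fastq"))
          con <- file(path, open = "wb")
          writeLines(er$fastq, con)
          close(con)
          if (w == "up") up_paths <- c(up_paths, path)
          else down_paths <- c(down_paths, path)
        }
      }
    }
    log_stage("simulate", strains = nrow(catalog$records),
              samples = nrow(sheet), conditions = length(conds))
    list(sc = sc, catalog = catalog, sheet = sheet, truths = truths,
         up = up_paths, down = down_paths)
  })

  bc <- run_stage("count", {
    bc <- count_run(sim$up, sim$down, sim$catalog, sim$sheet)
    write_artifact(data.frame(strain_id = rownames(bc$counts), bc$counts,
                              check.names = FALSE),
                   file.path(out_dir, "counts.tsv"), hash)
    write_artifact(bc$accounting, file.path(out_dir, "accounting.tsv"), hash)
    log_stage("count", reads = sum(bc$accounting$reads),
              hits = sum(bc$accounting$hits),
              ambiguous = sum(bc$accounting$ambiguous),
              unmatched = sum(bc$accounting$unmatched),
              no_tag = sum(bc$accounting$no_tag),
              unassigned = bc$unassigned)
    bc
  })

  contrasts <- run_stage("contrast", {
    out <- list()
    for (cond in unlist(cfg$simulate$conditions)) {
      for (ct in cfg$contrasts) {
        res <- contrast_stages(bc, sim$sheet, cond, ct$from, ct$to,
                               alpha_sig = cfg$thresholds$alpha_sig,
                               fold = cfg$thresholds$fold)
        key <- paste0(cond, "_", ct$from, "_", ct$to)
        out[[key]] <- res
        write_artifact(res, file.path(out_dir,
                                      paste0("contrast_", key, ".tsv")), hash)
        log_stage(paste0("contrast:", key), tested = nrow(res),
                  HP = sum(res$call == "HP"), HI = sum(res$call == "HI"))
      }
    }
    out
  })

  screen_calls <- NULL
  if (isTRUE(cfg$screen$enabled)) {
    screen_calls <- run_stage("screen", {
      sp <- simulate_plates(sim$catalog$records$strain_id,
                            fraction_reduced = cfg$screen$fraction_reduced,
                            mean_reduced = cfg$screen$mean_reduced,
                            noise_sd = cfg$screen$noise_sd,
                            plate_effect_sd = cfg$screen$plate_effect_sd,
                            seed = substream_seed(cfg$seed, "plates"))
      write_artifact(sp$plates, file.path(out_dir, "plates.tsv"), hash)
      scr <- colony_screen(sp$plates)
      write_artifact(scr$calls, file.path(out_dir, "screen_calls.tsv"), hash)
      log_stage("screen", strains = nrow(scr$calls),
                significant = sum(scr$calls$significant))
      scr$calls
    })
  }

  report$reconciliation <- with(as.data.frame(bc$accounting), all(
    reads == hits + ambiguous + unmatched + no_tag))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

random_index6 <- function(n, seed) {
  set.seed(substream_seed(seed, "indices"))
  repeat {
    idx <- random_tags(n, 6L)
    if (!anyDuplicated(idx)) return(idx)
  }
}

#' Audit a run directory for read-accounting consistency
#'
#' Re-reads the written accounting artifact (not in-memory state) and
#' checks that reads = hits + ambiguous + unmatched + no_tag per sample.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return TRUE invisibly, or a validation error.
#' @export
audit_run <- function(out_dir) {
  acct <- read.delim(file.path(out_dir, "accounting.tsv"),
                     comment.char = "#")
  ok <- acct$reads == acct$hits + acct$ambiguous + acct$unmatched +
    acct$no_tag
  if (!all(ok))
    bf_validation_error(paste0("accounting mismatch for sample(s): ",
      paste(acct$sample_id[!ok], collapse = ", ")))
  invisible(TRUE)
}
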