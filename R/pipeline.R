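# End-to-end study orchestration: simulate -> preprocess -> three
# longest-run tests, plus report writing and a replication harness.

#' Configuration for a complete simulated study
#'
#' Bundles the generator, preprocessing and Monte Carlo settings.
#'
#' @param generator a [sep_gen_config()].
#' @param preproc a [preproc_config()].
#' @param n_sims Monte Carlo simulations per test (default 1000).
#' @param alpha pointwise two-tailed significance level (default 0.05).
#' @param percentile run-length percentile for the threshold (default 95).
#' @param rho_override optional fixed lag-1 autocorrelation used for all
#'   three tests instead of the data estimate (reported alongside it).
#' @param output_dir optional directory for [write_report()].
#' @param report_format `"csv"` or `"json"` for the tabular outputs.
#' @param seed master seed; overrides `generator$seed` and seeds the three
#'   null simulations via derived sub-seeds.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(generator = sep_gen_config(),
                         preproc = preproc_config(),
                         n_sims = 1000, alpha = 0.05, percentile = 95,
                         rho_override = NULL, output_dir = NULL,
                         report_format = c("csv", "json"),
                         seed = NULL) {
  stopifnot(inherits(generator, "sep_gen_config"),
            inherits(preproc, "preproc_config"))
  report_format <- match.arg(report_format)
  if (generator$sampling_rate <= 2 * preproc$lowpass_hz) {
    stop_vicarsep("generator sampling rate must exceed twice the low-pass cutoff",
                  "vicarsep_invalid_parameter")
  }
  if (preproc$analysis_window[1] < generator$epoch_window[1] ||
      preproc$analysis_window[2] > generator$epoch_window[2]) {
    stop_vicarsep("analysis window must lie inside the epoch",
                  "vicarsep_invalid_parameter")
  }
  if (!is.null(seed)) generator$seed <- seed
  structure(list(generator = generator, preproc = preproc,
                 n_sims = n_sims, alpha = alpha, percentile = percentile,
                 rho_override = rho_override, output_dir = output_dir,
                 report_format = report_format,
                 seed = seed %||% generator$seed),
            class = "study_config")
}

#' Run a complete simulated study
#'
#' Generates the study, preprocesses every participant, builds the
#' contralateral, ipsilateral and interaction difference matrices and runs
#' the longest-run test on each. Fully deterministic given the config
#' seed.
#'
#' @param config a [study_config()].
#' @return object of class `"sep_study"`: `tests` (named list of three
#'   [sep_runtest()] fits), `grand_average` (data frame: `time_ms`,
#'   `condition`, `laterality`, `mean_uV`, `sem_uV`), `retained`,
#'   `dropped`, `rho` (data frame of estimates and the rho actually used),
#'   `seeds`, `config`, `version`.
#' @examples
#' \donttest{
#' cfg <- study_config(sep_gen_config(seed = 1), n_sims = 200)
#' st <- run_study(cfg)
#' st
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  study <- simulate_study(config$generator)
  dm <- sep_diff_matrices(study, config$preproc)
  mats <- dm[c("contra", "ipsi", "interaction")]
  seeds <- list(generator = config$generator$seed)
  tests <- list()
  for (i in seq_along(mats)) {
    lab <- names(mats)[i]
    seeds[[lab]] <- derive_seed(config$seed, i, salt = 1)
    tests[[lab]] <- sep_runtest(mats[[i]], rho = config$rho_override,
                                n_sims = config$n_sims,
                                alpha = config$alpha,
                                percentile = config$percentile,
                                seed = seeds[[lab]])
  }
  ga <- grand_average_table(dm$seps)
  rho <- data.frame(
    laterality = names(tests),
    rho_estimate = vapply(tests, function(t)
      as.numeric(t$rho_estimate), numeric(1)),
    rho_estimate_raw = vapply(tests, function(t)
      attr(t$rho_estimate, "raw") %||% NA_real_, numeric(1)),
    rho_used = vapply(tests, function(t) t$rho_used, numeric(1)),
    row.names = NULL)
  structure(list(tests = tests, grand_average = ga,
                 retained = dm$retained, dropped = dm$dropped,
                 rho = rho, seeds = seeds, config = config,
                 version = as.character(utils::packageVersion("vicarsep"))),
            class = "sep_study")
}

grand_average_table <- function(seps) {
  out <- list()
  for (k in c("Hand", "Surface")) for (lat in c("Contralateral",
                                                "Ipsilateral")) {
    ws <- Filter(function(w) w$condition == k && w$laterality == lat, seps)
    if (length(ws) == 0L) next
    vals <- do.call(rbind, lapply(ws, `[[`, "values"))
    out[[length(out) + 1L]] <- data.frame(
      time_ms = ws[[1]]$time_ms, condition = k, laterality = lat,
      mean_uV = colMeans(vals),
      sem_uV = apply(vals, 2, stats::sd) / sqrt(nrow(vals)))
  }
  do.call(rbind, out)
}

#' @export
print.sep_study <- function(x, ...) {
  cat(sprintf("Simulated SEP study (version %s): %d usable participants",
              x$version, nrow(x$retained)))
  if (length(x$dropped)) cat(sprintf(" (%d dropped)", length(x$dropped)))
  cat(sprintf("\n  mean retained trials: Hand %.1f, Surface %.1f\n",
              mean(x$retained$hand), mean(x$retained$surface)))
  for (lab in names(x$tests)) print(x$tests[[lab]])
  invisible(x)
}

#' Replicate a study configuration across seeds
#'
#' Runs [run_study()] `n_replicates` times under derived seeds and
#' tabulates, per laterality: whether a significant interval in the
#' expected direction was found, its Jaccard overlap with the generator's
#' true effect window, and the duration threshold used.
#'
#' @param config a [study_config()].
#' @param n_replicates number of replicate studies.
#' @param base_seed seed from which replicate seeds are derived.
#' @return object of class `"sep_replication"`: `table` (one row per
#'   replicate x laterality) plus the truth windows used.
#' @export
replicate_studies <- function(config, n_replicates, base_seed = 1) {
  stopifnot(inherits(config, "study_config"), n_replicates >= 1)
  gen <- config$generator
  truth <- list(
    contra = list(window = gen$effect_contra$window,
                  direction = if ((gen$effect_contra$hand_mean -
                                     gen$effect_contra$surface_mean) >= 0)
                    "positive" else "negative"),
    ipsi = list(window = gen$effect_ipsi$window,
                direction = if ((gen$effect_ipsi$hand_mean -
                                   gen$effect_ipsi$surface_mean) >= 0)
                  "positive" else "negative"))
  rows <- list()
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, i, salt = 2)
    cfg$generator$seed <- cfg$seed
    st <- run_study(cfg)
    for (lab in names(st$tests)) {
      fit <- st$tests[[lab]]
      tr <- truth[[lab]]
      ivs <- fit$intervals
      if (!is.null(tr)) ivs <- ivs[ivs$direction == tr$direction, ,
                                   drop = FALSE]
      ov <- if (is.null(tr) || nrow(ivs) == 0L) 0 else
        max(vapply(seq_len(nrow(ivs)), function(j)
          jaccard_overlap(c(ivs$start_ms[j], ivs$end_ms[j]), tr$window),
          numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, laterality = lab, seed = cfg$seed,
        significant = fit$significant,
        detected = nrow(ivs) > 0L,
        overlap_jaccard = ov,
        threshold_ms = fit$null$threshold_ms,
        rho_used = fit$rho_used)
    }
  }
  structure(list(table = do.call(rbind, rows), truth = truth,
                 n_replicates = n_replicates, base_seed = base_seed),
            class = "sep_replication")
}

jaccard_overlap <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- max(a[2], b[2]) - min(a[1], b[1])
  if (union <= 0) 0 else inter / union
}

#' @export
print.sep_replication <- function(x, ...) {
  cat(sprintf("Replication harness: %d replicates\n", x$n_replicates))
  for (lab in unique(x$table$laterality)) {
    tb <- x$table[x$table$laterality == lab, ]
    cat(sprintf("  %-11s detection rate %.2f, mean overlap %.2f, mean threshold %.1f ms\n",
                lab, mean(tb$detected), mean(tb$overlap_jaccard),
                mean(tb$threshold_ms)))
  }
  invisible(x)
}

# ---- report files ----------------------------------------------------------

intervals_table <- function(report) {
  out <- list()
  for (lab in names(report$tests)) {
    ivs <- report$tests[[lab]]$intervals
    if (nrow(ivs) == 0L) next
    out[[lab]] <- data.frame(laterality = lab,
                             ivs[c("start_ms", "end_ms", "direction",
                                   "mean_uV")],
                             threshold_ms = report$tests[[lab]]$null$threshold_ms,
                             rho_used = report$tests[[lab]]$rho_used)
  }
  if (length(out) == 0L) {
    return(data.frame(laterality = character(0), start_ms = numeric(0),
                      end_ms = numeric(0), direction = character(0),
                      mean_uV = numeric(0), threshold_ms = numeric(0),
                      rho_used = numeric(0)))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

null_runs_table <- function(report) {
  do.call(rbind, lapply(names(report$tests), function(lab) {
    rl <- report$tests[[lab]]$null$run_lengths
    data.frame(laterality = lab, sim_index = seq_along(rl),
               run_length_samples = rl)
  }))
}

write_table <- function(df, path, format) {
  if (format == "json") {
    jsonlite::write_json(df, sub("\\.csv$", ".json", path),
                         digits = NA, dataframe = "columns")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
}

#' Write a study report to disk
#'
#' Writes the significant intervals, grand-average waveforms, null
#' run-length distributions and a JSON manifest (config, seeds, version)
#' sufficient to regenerate the study bit-exactly.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed; defaults to the
#'   config's `output_dir`).
#' @param format `"csv"` or `"json"` (defaults to the config's choice).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir = NULL, format = NULL) {
  stopifnot(inherits(report, "sep_study"))
  dir <- dir %||% report$config$output_dir
  if (is.null(dir)) {
    stop_vicarsep("no output directory given", "vicarsep_io_error")
  }
  format <- format %||% report$config$report_format
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "json") "json" else "csv"
  files <- file.path(dir, c(paste0("intervals.", ext),
                            paste0("waveforms.", ext),
                            paste0("null_runs.", ext),
                            paste0("retained.", ext),
                            "manifest.json"))
  write_table(intervals_table(report), file.path(dir, "intervals.csv"),
              format)
  write_table(report$grand_average, file.path(dir, "waveforms.csv"),
              format)
  write_table(null_runs_table(report), file.path(dir, "null_runs.csv"),
              format)
  write_table(report$retained, file.path(dir, "retained.csv"), format)
  manifest <- list(config = strip_config(report$config),
                   seeds = report$seeds, rho = report$rho,
                   dropped = report$dropped, version = report$version)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(files)
}

# Recursively drop S3 classes so configs serialise as plain JSON objects.
strip_config <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_config) else x
}

#' Read back a written study report
#'
#' @param dir directory written by [write_report()].
#' @return list with `intervals`, `waveforms`, `null_runs`, `retained`
#'   data frames and the `manifest` list.
#' @export
read_report <- function(dir) {
  read_one <- function(stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    js <- file.path(dir, paste0(stem, ".json"))
    if (file.exists(csv)) {
      utils::read.csv(csv)
    } else {
      as.data.frame(jsonlite::read_json(js, simplifyVector = TRUE))
    }
  }
  list(intervals = read_one("intervals"),
       waveforms = read_one("waveforms"),
       null_runs = read_one("null_runs"),
       retained = read_one("retained"),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

# ---- epoch container (plain text) ------------------------------------------

#' Write epoched study data as a plain-text container
#'
#' One CSV per participant (trial metadata columns followed by one column
#' per sample) plus a JSON manifest with the time axis, channels, sampling
#' rate and reference.
#'
#' @param study an `"epochset_list"` or single [epochset()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_epochs <- function(study, dir) {
  if (inherits(study, "epochset")) study <- list(study)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  first <- study[[1]]
  manifest <- list(participants = vapply(study, `[[`, character(1),
                                         "participant_id"),
                   time_ms = first$time_ms, channels = first$channels,
                   sampling_rate = first$sampling_rate,
                   reference = first$reference)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (es in study) {
    d <- dim(es$data)
    flat <- matrix(aperm(es$data, c(2, 1, 3)), d[1] * d[2], d[3])
    df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                     channel = rep(es$channels, d[1]),
                     condition = rep(es$condition, each = d[2]),
                     hand = rep(es$hand, each = d[2]),
                     is_artifact = rep(es$is_artifact, each = d[2]))
    df <- cbind(df, as.data.frame(flat))
    utils::write.csv(df, file.path(dir, paste0(es$participant_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a plain-text epoch container
#'
#' @param dir directory written by [write_epochs()].
#' @return an `"epochset_list"`.
#' @export
read_epochs <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  study <- lapply(manifest$participants, function(pid) {
    df <- utils::read.csv(file.path(dir, paste0(pid, ".csv")))
    meta <- df[, 1:5]
    flat <- as.matrix(df[, -(1:5)])
    Tn <- max(meta$trial)
    C <- length(manifest$channels)
    S <- length(manifest$time_ms)
    data <- aperm(array(flat, c(C, Tn, S)), c(2, 1, 3))
    tr1 <- meta$channel == meta$channel[1]
    epochset(data, manifest$time_ms,
             condition = meta$condition[tr1], hand = meta$hand[tr1],
             channels = manifest$channels,
             sampling_rate = manifest$sampling_rate,
             reference = manifest$reference,
             is_artifact = meta$is_artifact[tr1],
             participant_id = pid)
  })
  names(study) <- manifest$participants
  structure(study, class = "epochset_list")
}
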