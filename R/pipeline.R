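# Run configuration and the end-to-end desk-scale replication driver.

run_config_defaults <- function() {
  list(
    seed = 1L,
    sample_rate = 8000,
    n_female = 60L, n_male_court = 66L, n_male_comp = 39L,
    female_duration = 2,
    noise_snr_db = 20,
    n_per_condition = 45L,
    write_wavs = TRUE
  )
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration for [run_replication()]. Only keys known to
#' the schema are accepted (unknown keys are an error, catching typos before
#' any stage runs); missing keys take their defaults.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A validated named list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop("read_run_config: unknown config key(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  num <- c("seed", "sample_rate", "n_female", "n_male_court", "n_male_comp",
           "female_duration", "noise_snr_db", "n_per_condition")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]]))
      stop("read_run_config: '", k, "' must be a single finite number")
  if (cfg$sample_rate <= 1000) stop("read_run_config: sample_rate too low")
  if (any(unlist(cfg[c("n_female", "n_male_court", "n_male_comp")]) < 0))
    stop("read_run_config: corpus counts must be >= 0")
  structure(cfg, class = "run_config")
}

#' Desk-scale replication of the screening study
#'
#' Runs the full pipeline end to end: (1) generate a synthetic corpus of the
#' three natural signal classes and write WAVs plus ground truth; (2) extract
#' per-signal MVF/pulse-rate descriptors and summarize per class; (3)
#' synthesize the seven disruptive signals; (4) simulate the playback
#' screening parameterized by the published per-condition rates and delays;
#' (5) aggregate, test (Kruskal-Wallis + Dunn against control) and write a
#' disruption report. All randomness derives from \code{seed}; two runs with
#' the same seed produce identical report JSONs.
#'
#' @param out_dir Output directory.
#' @param config A \code{run_config} (see [read_run_config()]), or \code{NULL}
#'   for defaults.
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list: \code{corpus_summary}, \code{trials},
#'   \code{condition_summary}, \code{kw}, \code{dunn}, \code{report},
#'   \code{report_path}.
#' @export
run_replication <- function(out_dir, config = NULL, seed = NULL) {
  cfg <- if (is.null(config)) read_run_config() else config
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(seed)) cfg$seed <- seed
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("run_replication: cannot create ", out_dir)

  pop <- population_params(noise_snr_db = cfg$noise_snr_db)
  corpus <- gen_corpus(
    file.path(out_dir, "corpus"),
    n_female = cfg$n_female, n_male_court = cfg$n_male_court,
    n_male_comp = cfg$n_male_comp, pop = pop,
    sample_rate = cfg$sample_rate, seed = cfg$seed,
    female_duration = cfg$female_duration, write_wavs = cfg$write_wavs
  )
  corpus_summary <- summarize_corpus(
    corpus, out_csv = file.path(out_dir, "class_summary.csv"))

  disruptors <- make_all_seven(sample_rate = cfg$sample_rate,
                               seed = cfg$seed + 1L, rms_normalize = TRUE)
  if (cfg$write_wavs) {
    ddir <- file.path(out_dir, "disruptors")
    dir.create(ddir, showWarnings = FALSE)
    for (nm in names(disruptors))
      write_wav(disruptors[[nm]], file.path(ddir, paste0(nm, ".wav")))
  }

  trials <- simulate_experiment(table1_sim_params(), cfg$n_per_condition,
                                seed = cfg$seed + 2L)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  cond <- summarize_conditions(trials)
  groups <- split(trials$delay_s[trials$replied], trials$condition[trials$replied])
  groups <- groups[lengths(groups) > 0]
  kw <- kruskal_wallis(groups)
  ctrl_idx <- which(names(groups) == "Control")
  comps <- if (length(ctrl_idx) == 1)
    cbind(ctrl_idx, setdiff(seq_along(groups), ctrl_idx)) else NULL
  dunn <- dunn_pairwise(groups, comparisons = comps)
  report <- disruption_report(cond, kw = kw, dunn = dunn)

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      class_summary = corpus_summary$summary,
      condition_summary = cond,
      kruskal_wallis = list(H = kw$H, df = kw$df, p = kw$p),
      dunn = dunn,
      disruption = report$table
    ),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(corpus_summary = corpus_summary, trials = trials,
                 condition_summary = cond, kw = kw, dunn = dunn,
                 report = report, report_path = report_path))
}
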