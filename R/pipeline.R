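#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run: cohort size and age range,
#' the synthetic coupling profile, artifact-rejection criteria, wPLI
#' frequency grid, threshold proportion, small-world convention, additive
#' model basis dimensions, FDR level and the moderate-effect cut.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_subjects cohort size (default 39).
#' @param age_range numeric length 2 (default c(20, 81)).
#' @param conditions task conditions (default shape, binding).
#' @param profile a [coupling_profile()].
#' @param criteria a [rejection_criteria()].
#' @param freqs wPLI center-frequency grid (default 1:48 Hz).
#' @param proportion edge retention fraction (default 0.55).
#' @param sw_convention small-world convention (default "as_printed").
#' @param k_cognitive,k_graph spline basis dimensions (10 / 12).
#' @param q FDR level (default 0.05).
#' @param min_abs_r moderate-effect threshold (default 0.400).
#' @param n_epochs fixed epoch count per subject-condition; `NULL` (the
#'   default) draws counts from the truncated-normal epoch model.
#' @param write_spectra also serialize every narrowband wPLI matrix (one
#'   CSV per center frequency) next to the band matrices; off by default
#'   (48 files per subject and condition).
#' @param artifact_rate fraction of extra epochs contaminated with
#'   amplitude artifacts before preprocessing (default 0.08).
#' @param outdir output directory for all stage artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 39, age_range = c(20, 81),
                       conditions = c("shape", "binding"),
                       profile = default_coupling_profile(),
                       criteria = rejection_criteria(),
                       freqs = 1:48, proportion = 0.55,
                       sw_convention = c("as_printed", "watts_strogatz"),
                       k_cognitive = 10, k_graph = 12,
                       q = 0.05, min_abs_r = 0.400,
                       n_epochs = NULL, artifact_rate = 0.08,
                       write_spectra = FALSE,
                       outdir = tempfile("bindnet_run_")) {
  sw_convention <- match.arg(sw_convention)
  stopifnot(inherits(profile, "coupling_profile"),
            inherits(criteria, "rejection_criteria"),
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 age_range = age_range, conditions = conditions,
                 profile = profile, criteria = criteria,
                 freqs = freqs, proportion = proportion,
                 sw_convention = sw_convention,
                 k_cognitive = k_cognitive, k_graph = k_graph,
                 q = q, min_abs_r = min_abs_r,
                 n_epochs = n_epochs, artifact_rate = artifact_rate,
                 write_spectra = isTRUE(write_spectra),
                 outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration as flat key-value text
#'
#' Serializes a [run_config()] to a plain-text file with one `key = value`
#' line per field; structured fields (coupling profile, criteria, band
#' grid) are stored as single-line JSON values. `read_run_config()`
#' restores a configuration with full round-trip fidelity.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  j <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  lines <- c(
    paste("seed =", config$seed),
    paste("n_subjects =", config$n_subjects),
    paste("age_range =", j(config$age_range)),
    paste("conditions =", j(config$conditions)),
    paste("profile =", {
      # named atomic vectors must become objects (not arrays) in JSON
      pl <- unclass(config$profile)
      pl$amplitudes <- as.list(pl$amplitudes)
      pl$band_freqs <- as.list(pl$band_freqs)
      j(pl)
    }),
    paste("criteria =", j(unclass(config$criteria))),
    paste("freqs =", j(config$freqs)),
    paste("proportion =", config$proportion),
    paste("sw_convention =", config$sw_convention),
    paste("k_cognitive =", config$k_cognitive),
    paste("k_graph =", config$k_graph),
    paste("q =", config$q),
    paste("min_abs_r =", config$min_abs_r),
    paste("n_epochs =", if (is.null(config$n_epochs)) "null" else config$n_epochs),
    paste("artifact_rate =", config$artifact_rate),
    paste("write_spectra =", tolower(config$write_spectra)),
    paste("outdir =", config$outdir)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(" = ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get <- function(k) vals[match(k, keys)]
  fromj <- function(k) jsonlite::fromJSON(get(k), simplifyVector = TRUE)
  prof_raw <- jsonlite::fromJSON(get("profile"), simplifyVector = FALSE)
  prof <- coupling_profile(
    bands = lapply(prof_raw$bands, function(b) {
      list(pairs = lapply(b$pairs, unlist),
           lag = b$lag, strength = b$strength)
    }),
    amplitudes = unlist(prof_raw$amplitudes),
    band_freqs = unlist(prof_raw$band_freqs),
    noise = prof_raw$noise,
    drift_sd = prof_raw$drift_sd,
    age_range = unlist(prof_raw$age_range)
  )
  crit_raw <- fromj("criteria")
  ne <- get("n_epochs")
  run_config(
    seed = as.integer(get("seed")),
    n_subjects = as.numeric(get("n_subjects")),
    age_range = fromj("age_range"),
    conditions = fromj("conditions"),
    profile = prof,
    criteria = do.call(rejection_criteria, as.list(crit_raw)),
    freqs = fromj("freqs"),
    proportion = as.numeric(get("proportion")),
    sw_convention = get("sw_convention"),
    k_cognitive = as.numeric(get("k_cognitive")),
    k_graph = as.numeric(get("k_graph")),
    q = as.numeric(get("q")),
    min_abs_r = as.numeric(get("min_abs_r")),
    n_epochs = if (identical(ne, "null")) NULL else as.numeric(ne),
    artifact_rate = as.numeric(get("artifact_rate")),
    write_spectra = identical(get("write_spectra"), "true"),
    outdir = get("outdir")
  )
}

# deterministic per-(subject, condition, purpose) sub-seed below 2^31
sub_seed <- function(seed, i, ci, purpose = 0) {
  (as.numeric(seed) + 7919 * i + 104729 * ci + 15485863 * purpose) %%
    2147483647
}

edf_name <- function(dir, sid, cond) file.path(dir, paste0(sid, "_", cond, ".edf"))

#' Stage 1: simulate cohort, trial sequences and raw epochs
#'
#' Writes `cohort.csv`, `trials.csv`, and one EDF file plus JSON sidecar
#' (subject metadata, true per-band coupling strengths, seeds) per
#' subject and condition under `outdir/edf/`. A fraction of extra epochs
#' is contaminated with amplitude artifacts so the preprocessing stage
#' has realistic work to do.
#'
#' @param config a [run_config()].
#' @return Invisibly, the cohort data.frame.
#' @export
stage_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  edf_dir <- file.path(config$outdir, "edf")
  dir.create(edf_dir, showWarnings = FALSE)

  cohort <- simulate_cohort(config$n_subjects, config$age_range[1],
                            config$age_range[2], seed = config$seed)
  write.csv(cohort, file.path(config$outdir, "cohort.csv"), row.names = FALSE)

  trials <- list()
  for (i in seq_len(nrow(cohort))) {
    tr <- simulate_trials(seed = sub_seed(config$seed, i, 0, 1))
    tr$subject_id <- cohort$subject_id[i]
    trials[[i]] <- tr
  }
  write.csv(do.call(rbind, trials), file.path(config$outdir, "trials.csv"),
            row.names = FALSE)

  for (i in seq_len(nrow(cohort))) {
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      sd_ep <- sub_seed(config$seed, i, ci, 2)
      # target count of clean epochs, plus extras to contaminate
      set.seed(sd_ep)
      n_clean <- if (is.null(config$n_epochs)) {
        draw_epoch_count(if (cond %in% c("shape", "binding")) cond else "shape")
      } else config$n_epochs
      n_art <- ceiling(config$artifact_rate * n_clean)
      ep <- simulate_epochs(cohort[i, ], cond, config$profile,
                            n_epochs = n_clean + n_art,
                            seed = sub_seed(config$seed, i, ci, 3))
      if (n_art > 0) {
        set.seed(sub_seed(config$seed, i, ci, 4))
        bad <- sample(n_epochs(ep), n_art)
        ep <- inject_artifacts(ep, "amplitude", bad, magnitude = 120,
                               seed = sub_seed(config$seed, i, ci, 5))
      }
      path <- edf_name(edf_dir, cohort$subject_id[i], cond)
      write_edf(ep, path)
      g_true <- vapply(canonical_bands()$band, function(b) {
        coupling_strength(config$profile, b, cohort$age[i])
      }, numeric(1))
      jsonlite::write_json(
        list(subject = as.list(cohort[i, ]), condition = cond,
             n_epochs = n_epochs(ep), n_contaminated = n_art,
             true_coupling = as.list(g_true),
             seed = sub_seed(config$seed, i, ci, 3)),
        sub("\\.edf$", ".json", path), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(cohort)
}

#' Stage 2: artifact rejection
#'
#' Reads the raw per-subject EDF files, applies [reject_epochs()] with the
#' configured criteria, writes cleaned EDF files under `outdir/clean/` and
#' a long-format `rejection_report.csv` (subject, condition, epoch, kept,
#' criteria fired).
#'
#' @param config a [run_config()].
#' @return Invisibly, the rejection report data.frame.
#' @export
stage_preprocess <- function(config) {
  cohort <- read.csv(file.path(config$outdir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  edf_dir <- file.path(config$outdir, "edf")
  clean_dir <- file.path(config$outdir, "clean")
  dir.create(clean_dir, showWarnings = FALSE)
  report <- list()
  for (sid in cohort$subject_id) {
    for (cond in config$conditions) {
      ep <- read_edf_epochs(edf_name(edf_dir, sid, cond))
      res <- reject_epochs(ep, config$criteria)
      write_edf(res$epochs, edf_name(clean_dir, sid, cond))
      pe <- res$log$per_epoch
      pe$subject_id <- sid
      pe$condition <- cond
      report[[length(report) + 1]] <- pe
    }
  }
  report <- do.call(rbind, report)
  report <- report[, c("subject_id", "condition", "epoch", "kept",
                       "violations")]
  write.csv(report, file.path(config$outdir, "rejection_report.csv"),
            row.names = FALSE)
  invisible(report)
}

# label-annotated matrix CSV helpers
write_matrix_csv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$node
  m
}

#' Stage 3: wPLI connectivity
#'
#' Reads cleaned epochs, estimates the narrowband wPLI spectrum on the
#' configured frequency grid, aggregates the canonical bands available on
#' that grid, and writes one matrix CSV per subject, condition and band
#' under `outdir/connectivity/` plus a JSON manifest of parameters.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
stage_connect <- function(config) {
  cohort <- read.csv(file.path(config$outdir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  clean_dir <- file.path(config$outdir, "clean")
  conn_dir <- file.path(config$outdir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  tab <- canonical_bands()
  bands <- tab$band[vapply(tab$centers, function(ctr)
    all(ctr %in% config$freqs), logical(1))]
  files <- character()
  for (sid in cohort$subject_id) {
    for (cond in config$conditions) {
      ep <- read_edf_epochs(edf_name(clean_dir, sid, cond))
      spec <- suppressMessages(wpli_spectrum(ep, freqs = config$freqs))
      if (isTRUE(config$write_spectra)) {
        for (fi in seq_along(spec$freqs)) {
          m <- spec$w[fi, , ]
          write_matrix_csv(m, file.path(conn_dir, sprintf(
            "%s_%s_f%02d.csv", sid, cond, spec$freqs[fi])))
        }
      }
      for (b in bands) {
        m <- aggregate_band(spec, b)
        f <- file.path(conn_dir, paste0(sid, "_", cond, "_", b, ".csv"))
        write_matrix_csv(m, f)
        files <- c(files, f)
      }
    }
  }
  manifest <- list(freqs = config$freqs, bandwidth = 1, trim = 0.25,
                   pooling = "time", bands = bands,
                   n_matrices = length(files),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(conn_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Stage 4: graph metrics
#'
#' Thresholds every band matrix at the configured proportion and computes
#' the integration (CPL, global efficiency, betweenness), segregation
#' (clustering, modules, participation) and small-world metrics, written
#' as a tidy long `metrics.csv` (subject, condition, band, scope, node,
#' metric, value).
#'
#' @param config a [run_config()].
#' @return Invisibly, the tidy metrics data.frame.
#' @export
stage_graph <- function(config) {
  cohort <- read.csv(file.path(config$outdir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  conn_dir <- file.path(config$outdir, "connectivity")
  manifest <- jsonlite::fromJSON(file.path(conn_dir, "manifest.json"))
  bands <- manifest$bands
  rows <- list()
  add <- function(sid, cond, band, scope, node, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = sid, condition = cond, band = band, scope = scope,
      node = node, metric = metric, value = unname(value),
      stringsAsFactors = FALSE)
  }
  for (sid in cohort$subject_id) {
    for (cond in config$conditions) {
      for (b in bands) {
        m <- read_matrix_csv(
          file.path(conn_dir, paste0(sid, "_", cond, "_", b, ".csv")))
        g <- threshold_proportional(m, config$proportion)
        pm <- path_metrics(g)
        cl <- clustering_onnela(g)
        bc <- betweenness_w(g)
        cm <- communities_louvain(g, seed = sub_seed(config$seed,
                                                     match(sid, cohort$subject_id),
                                                     match(cond, config$conditions), 6))
        hb <- hubness(g, cm$membership)
        sw <- small_world(g, convention = config$sw_convention,
                          seed = config$seed)
        add(sid, cond, b, "global", "", "cpl", pm$L)
        add(sid, cond, b, "global", "", "geff", pm$E_glob)
        add(sid, cond, b, "global", "", "cc_mean", cl$C)
        add(sid, cond, b, "global", "", "modularity_q", cm$Q)
        add(sid, cond, b, "global", "", "gamma", sw$gamma)
        add(sid, cond, b, "global", "", "lambda", sw$lambda)
        add(sid, cond, b, "global", "", "sigma", sw$sigma)
        lbl <- g$labels
        add(sid, cond, b, "node", lbl, "bc", bc)
        add(sid, cond, b, "node", lbl, "cc", cl$cc)
        add(sid, cond, b, "node", lbl, "module_z", cm$module_z)
        add(sid, cond, b, "node", lbl, "participation", hb$participation)
        add(sid, cond, b, "node", lbl, "hub_flag", as.numeric(hb$hub_flag))
      }
    }
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(config$outdir, "metrics.csv"),
            row.names = FALSE)
  invisible(metrics)
}

#' Stage 5: age-effect models and correlation screen
#'
#' Produces the summary tables: `table1.csv` (cohort demographics plus
#' additive-model age effects on MMSE and BDI), `table2.csv`
#' (per-outcome additive-model statistics for behavioural, cognitive and
#' global graph outcomes), and `correlations.csv` (the age-partialled
#' screen of global graph metrics against cognitive and behavioural
#' scores, BH-adjusted within metric family). When the cohort is smaller
#' than the spline basis the model stage is skipped with a warning.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the three data.frames.
#' @export
stage_stats <- function(config) {
  cohort <- read.csv(file.path(config$outdir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  metrics <- read.csv(file.path(config$outdir, "metrics.csv"),
                      stringsAsFactors = FALSE)
  n <- nrow(cohort)

  msd <- function(x) sprintf("%.2f (%.2f)", mean(x), sd(x))
  table1 <- data.frame(
    row = c("n", "Age", "Education", "Sex (F/M)", "MMSE", "BDI"),
    value = c(n, msd(cohort$age), msd(cohort$education),
              paste0(sum(cohort$sex == "F"), "/", sum(cohort$sex == "M")),
              msd(cohort$mmse), msd(cohort$bdi)),
    stringsAsFactors = FALSE)

  gam_possible <- n >= max(config$k_cognitive, config$k_graph)
  gam_row <- function(fit) {
    data.frame(outcome = fit$outcome,
               intercept_estimate = fit$intercept[["estimate"]],
               intercept_se = fit$intercept[["se"]],
               intercept_t = fit$intercept[["t"]],
               intercept_p = fit$intercept[["p"]],
               edf = fit$smooth[["edf"]], ref_df = fit$smooth[["ref_df"]],
               F_value = fit$smooth[["F"]], p_value = fit$smooth[["p"]],
               k = fit$k, n = fit$n, stringsAsFactors = FALSE)
  }

  # global graph metrics in wide form: one column per condition x band x metric
  glob <- metrics[metrics$scope == "global", ]
  glob$col <- paste(glob$metric, glob$band, glob$condition, sep = "_")
  wide <- cohort[, c("subject_id", "age", "mmse", "bdi",
                     grep("^z_|^acc_|^rt_", names(cohort), value = TRUE))]
  for (cc in unique(glob$col)) {
    sub <- glob[glob$col == cc, c("subject_id", "value")]
    wide[[cc]] <- sub$value[match(wide$subject_id, sub$subject_id)]
  }

  if (!gam_possible) {
    warning("n (", n, ") below spline basis dimension; ",
            "model stage skipped")
    table2 <- data.frame()
    correlations <- data.frame()
  } else {
    cog_outcomes <- c("mmse", "bdi",
                      grep("^z_|^acc_|^rt_", names(cohort), value = TRUE))
    graph_outcomes <- unique(glob$col[glob$metric %in%
                                        c("cpl", "geff", "cc_mean", "sigma")])
    fits <- c(
      lapply(cog_outcomes, function(o)
        fit_age_gam(wide[[o]], wide$age, k = config$k_cognitive, outcome = o)),
      lapply(graph_outcomes, function(o)
        fit_age_gam(wide[[o]], wide$age, k = config$k_graph, outcome = o))
    )
    table2 <- do.call(rbind, lapply(fits, gam_row))

    fam <- c(cpl = "integration", geff = "integration",
             cc_mean = "segregation", sigma = "global")
    base <- sub("_(delta|theta|alpha|beta|gamma)_.*$", "", graph_outcomes)
    family <- stats::setNames(unname(fam[base]), graph_outcomes)
    scores <- c(grep("^z_|^acc_|^rt_", names(cohort), value = TRUE),
                "mmse", "bdi")
    correlations <- screen_correlations(
      wide, metrics = graph_outcomes, scores = scores, family = family,
      k = config$k_graph, min_abs_r = config$min_abs_r, q = config$q)
  }

  write.csv(table1, file.path(config$outdir, "table1.csv"), row.names = FALSE)
  write.csv(table2, file.path(config$outdir, "table2.csv"), row.names = FALSE)
  write.csv(correlations, file.path(config$outdir, "correlations.csv"),
            row.names = FALSE)
  invisible(list(table1 = table1, table2 = table2,
                 correlations = correlations))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, connect, graph and stats in order, each
#' stage reading only the files of its predecessors (so any stage can be
#' rerun in isolation), and writes `manifest.json` with the configuration,
#' an MD5 digest of every output file, and per-stage wall times. The run
#' is a pure function of the configuration: identical configs yield
#' byte-identical CSV outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$outdir, "config.txt"))
  stages <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 connect = stage_connect, graph = stage_graph,
                 stats = stage_stats)
  timing <- list()
  warns <- character()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      tryCatch(stages[[nm]](config), error = function(e) {
        stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        # record for the manifest; the warning still propagates
        warns <<- c(warns, paste0(nm, ": ", conditionMessage(w)))
      })
    timing[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  top_files <- list.files(config$outdir, pattern = "\\.csv$",
                          full.names = TRUE)
  manifest <- list(
    config_file = "config.txt",
    config_md5 = unname(tools::md5sum(file.path(config$outdir, "config.txt"))),
    seed = config$seed,
    version = as.character(utils::packageVersion("bindnet")),
    stage_seconds = timing,
    warnings = warns,
    output_md5 = as.list(tools::md5sum(top_files))
  )
  names(manifest$output_md5) <- basename(top_files)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
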