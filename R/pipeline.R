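# Orchestration: ties dataset generation/loading, feature extraction (GPA
# landmarks or GP-LVM image features), paired cross-testing with ARD
# classifiers, rank summaries and saliency significance masks into one
# reproducible run, plus a command-line surface.
#
# Seed scheme: each stage s draws its seed as global_seed + 101 * s, so any
# stage can be reproduced in isolation.

stage_seed <- function(seed, stage) as.integer(seed + 101L * stage)

config_hash <- function(config) {
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum((v * (seq_along(v) %% 97 + 1)) %% 4294967291) %%
            4294967291)
}

#' Pipeline configuration
#'
#' @param dataset A [synth_spec()] (the dataset is generated) or a directory
#'   path written by [write_dataset()].
#' @param feature_mode `"GPA"` (aligned landmark shapes), `"Top-GPLVM"`
#'   (highest-ARD latent image features) or `"Sel-GPLVM"` (highest-ARD
#'   features that pass the artifact screen).  A CNN feature path is not
#'   part of this package and is rejected.
#' @param classifier `"GPC"` or `"HMC-MLP"`.
#' @param n_folds,n_reshuffles Cross-testing plan parameters.
#' @param n_features Number of latent dimensions fed to the classifier in
#'   the GP-LVM modes.
#' @param gplvm_latent_dim,gplvm_inducing,gplvm_iterations GP-LVM size and
#'   optimizer budget.
#' @param saliency_k,saliency_n,saliency_threshold Saliency-test kernel
#'   size, resample count and p-value threshold.
#' @param out_dir Report directory (created).
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = synth_spec(),
                            feature_mode = c("GPA", "Top-GPLVM", "Sel-GPLVM"),
                            classifier = c("GPC", "HMC-MLP"),
                            n_folds = 10L, n_reshuffles = 10L,
                            n_features = 14L,
                            gplvm_latent_dim = 12L, gplvm_inducing = 40L,
                            gplvm_iterations = 300L,
                            saliency_k = 5L, saliency_n = 1000L,
                            saliency_threshold = 0.001,
                            out_dir = NULL, seed = 1L) {
  if (is.character(feature_mode) && toupper(feature_mode[1]) == "CNN")
    ms_stop(paste("the CNN feature/classifier path is out of scope for this",
                  "package; use GPA, Top-GPLVM or Sel-GPLVM (externally",
                  "produced CNN saliency maps can still be tested with",
                  "pvalue_map())"), "morphsal_config_error")
  feature_mode <- match.arg(feature_mode)
  classifier <- match.arg(classifier)
  structure(list(dataset = dataset, feature_mode = feature_mode,
                 classifier = classifier, n_folds = as.integer(n_folds),
                 n_reshuffles = as.integer(n_reshuffles),
                 n_features = as.integer(n_features),
                 gplvm_latent_dim = as.integer(gplvm_latent_dim),
                 gplvm_inducing = as.integer(gplvm_inducing),
                 gplvm_iterations = as.integer(gplvm_iterations),
                 saliency_k = as.integer(saliency_k),
                 saliency_n = as.integer(saliency_n),
                 saliency_threshold = saliency_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run a full analysis pipeline
#'
#' Generates or loads the dataset, extracts the configured features, runs
#' paired cross-testing, summarizes ARD relevance ranks, and (for GP-LVM
#' modes) writes saliency maps with significance masks.  The run is
#' deterministic under a fixed config and seed; when `out_dir` is set, a
#' self-contained report directory is written.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: the dataset, features, plan,
#'   `crosstest` result, `rank_freqs`, per-landmark or per-dimension
#'   relevance, the screen report (Sel mode), and the config hash.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    ms_stop("config must be a pipeline_config", "morphsal_config_error")
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ms_stop(sprintf("pipeline stage '%s' failed [config %s]: %s",
                      name, hash, conditionMessage(e)), "morphsal_error"))
  }
  ds <- stage("dataset", {
    if (inherits(config$dataset, "synth_spec")) generate_dataset(config$dataset)
    else read_dataset(config$dataset)
  })
  labels <- ds$labels
  screen <- NULL
  gfit <- NULL
  if (config$feature_mode == "GPA") {
    feats <- stage("features", gpa(ds$landmarks)$feature_matrix)
  } else {
    Y <- flatten_images(ds)
    gfit <- stage("gplvm", fit_gplvm(Y, config$gplvm_latent_dim,
                                     config$gplvm_inducing,
                                     config$gplvm_iterations,
                                     seed = stage_seed(config$seed, 1L)))
    rk <- rank_dimensions(gfit)
    nf <- min(config$n_features, gfit$latent_dim)
    if (config$feature_mode == "Top-GPLVM") {
      sel <- rk[seq_len(nf)]
    } else {
      fg <- foreground_mask(Y)
      screen <- stage("screen", screen_dimensions(
        gfit, fg, top_k = gfit$latent_dim, n_sel = nf,
        k = config$saliency_k, n_resamples = config$saliency_n,
        threshold = config$saliency_threshold,
        seed = stage_seed(config$seed, 2L)))
      sel <- screen$selected
    }
    feats <- gfit$means[, sel, drop = FALSE]
    colnames(feats) <- paste0("F", sel)
  }
  plan <- stage("plan", make_plan(labels, config$n_folds, config$n_reshuffles,
                                  seed = stage_seed(config$seed, 3L)))
  ct <- stage("crosstest", cross_test(
    feats, labels, plan,
    classifier = if (config$classifier == "GPC") "gpc" else "hmc_mlp",
    seed = stage_seed(config$seed, 4L)))
  rf <- stage("ranks", rank_frequencies(ct$relevance,
                                        top_ranks = min(5L, ncol(feats))))
  lrel <- NULL
  if (config$feature_mode == "GPA") {
    lrel <- stage("landmark-relevance", lapply(seq_along(ct$relevance),
      function(r) {
        if (config$classifier == "GPC")
          landmark_relevance(ct$relevance[[r]], "gpc", samples = feats)
        else {
          # combined MLP scales enter the summed-squares aggregation directly
          s <- ct$relevance[[r]]
          landmark_relevance(list(sigma1 = s, sigma2 = rep(0, length(s))),
                             "mlp")
        }
      }))
  }
  report <- structure(list(dataset = ds, features = feats, plan = plan,
                           crosstest = ct, rank_freqs = rf,
                           landmark_relevance = lrel, screen = screen,
                           gplvm = gfit, config = config, hash = hash),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report [%s]: %s + %s\n", x$hash,
              x$config$feature_mode, x$config$classifier))
  print(x$crosstest)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  m <- report$crosstest$metrics
  m$pipeline <- paste(cfg$feature_mode, cfg$classifier, sep = "+")
  utils::write.csv(m, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  rel <- do.call(rbind, report$crosstest$relevance)
  utils::write.csv(as.data.frame(rel), file.path(out_dir, "relevance.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$rank_freqs),
                   file.path(out_dir, "rank_frequencies.csv"))
  write_plan(report$plan, file.path(out_dir, "plan.csv"))
  if (!is.null(report$landmark_relevance)) {
    lr <- do.call(rbind, report$landmark_relevance)
    utils::write.csv(as.data.frame(lr),
                     file.path(out_dir, "landmark_relevance.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$screen)) {
    utils::write.csv(report$screen$report,
                     file.path(out_dir, "dimension_screen.csv"),
                     row.names = FALSE)
    for (i in seq_along(report$screen$maps)) {
      sm <- report$screen$maps[[i]]
      v <- sal_values(sm)
      png::writePNG(v / max(v, 1e-12),
                    file.path(out_dir, sprintf("saliency_%s.png",
                                               sm$source_tag)))
      write_pvalue_map(report$screen$pmaps[[i]],
                       file.path(out_dir, sprintf("saliency_%s",
                                                  sm$source_tag)))
    }
  }
  meta <- c(paste0("config_hash=", report$hash),
            paste0("seed=", cfg$seed),
            paste0("feature_mode=", cfg$feature_mode),
            paste0("classifier=", cfg$classifier),
            paste0("n_folds=", cfg$n_folds),
            paste0("n_reshuffles=", cfg$n_reshuffles),
            paste0("saliency_k=", cfg$saliency_k),
            paste0("saliency_n=", cfg$saliency_n),
            paste0("saliency_threshold=", cfg$saliency_threshold),
            paste0("package_version=",
                   as.character(utils::packageVersion("morphsal"))),
            paste0("r_version=", R.version.string))
  writeLines(meta, file.path(out_dir, "run_metadata.txt"))
  invisible(out_dir)
}

cli_usage <- function() {
  paste(
    "usage: morphsal <command> [--flag value ...]",
    "commands:",
    "  simulate      --out DIR [--preset table1] [--side N] [--seed S]",
    "  gpa           --in DATASET_DIR --out FEATURES.csv",
    "  gplvm         --in DATASET_DIR --out DIR [--latent L] [--inducing M]",
    "                [--iterations I] [--seed S]",
    "  saliency-test --in MAP.csv --out PREFIX [--k K] [--n N]",
    "                [--threshold T] [--seed S]",
    "  evaluate      --pred-a A.csv --pred-b B.csv --true T.csv",
    "  run-all       --out DIR [--mode GPA|Top-GPLVM|Sel-GPLVM]",
    "                [--classifier GPC|HMC-MLP] [--in DATASET_DIR]",
    "                [--folds F] [--reshuffles R] [--seed S]",
    sep = "\n")
}

cli_parse <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      return(structure(list(), bad = a))
    if (i + 1 > length(argv))
      return(structure(list(), bad = a))
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Thin argv-driven surface over the package functions; see the shipped
#' wrapper script `inst/cli/morphsal`.  Subcommands: `simulate`, `gpa`,
#' `gplvm`, `saliency-test`, `evaluate`, `run-all`.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code (0 success, 1 error, 2 usage), invisibly.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  t0 <- Sys.time()
  emit <- function(...) message(sprintf(...))
  if (length(argv) == 0) { message(cli_usage()); return(invisible(2L)) }
  cmd <- argv[1]
  flags <- cli_parse(argv[-1])
  if (!is.null(attr(flags, "bad"))) {
    message("unknown or incomplete flag: ", attr(flags, "bad"))
    message(cli_usage())
    return(invisible(2L))
  }
  fl <- function(name, default = NULL) flags[[name]] %||% default
  need <- function(name) {
    v <- flags[[name]]
    if (is.null(v)) ms_stop(sprintf("missing required flag --%s", name),
                            "morphsal_config_error")
    v
  }
  code <- tryCatch({
    switch(cmd,
      "simulate" = {
        seed <- as.integer(fl("seed", "1"))
        side <- as.integer(fl("side", "64"))
        preset <- fl("preset", "table1")
        if (preset != "table1")
          ms_stop(sprintf("unknown preset '%s'", preset),
                  "morphsal_config_error")
        sp <- synth_spec(image_side = side, seed = seed)
        ds <- generate_dataset(sp)
        write_dataset(ds, need("out"))
        emit("simulate: wrote %d specimens to %s", length(ds$images),
             need("out"))
        0L
      },
      "gpa" = {
        ds <- read_dataset(need("in"))
        sh <- gpa(ds$landmarks)
        write_feature_matrix(sh, need("out"))
        emit("gpa: wrote %dx%d feature matrix", nrow(sh$feature_matrix),
             ncol(sh$feature_matrix))
        0L
      },
      "gplvm" = {
        ds <- read_dataset(need("in"))
        fit <- fit_gplvm(flatten_images(ds),
                         latent_dim = as.integer(fl("latent", "12")),
                         n_inducing = as.integer(fl("inducing", "40")),
                         iterations = as.integer(fl("iterations", "300")),
                         seed = as.integer(fl("seed", "1")))
        write_latent(fit, need("out"))
        emit("gplvm: bound %.2f, wrote latent representation", fit$bound)
        0L
      },
      "saliency-test" = {
        sm <- read_saliency(need("in"))
        pm <- pvalue_map(sm, k = as.integer(fl("k", "5")),
                         n_resamples = as.integer(fl("n", "10000")),
                         threshold = as.numeric(fl("threshold", "0.001")),
                         seed = as.integer(fl("seed", "1")))
        write_pvalue_map(pm, need("out"))
        emit("saliency-test: %d significant pixels", sum(pm$mask))
        0L
      },
      "evaluate" = {
        rd <- function(p) utils::read.csv(p)[[1]]
        a <- rd(need("pred-a")); b <- rd(need("pred-b")); tr <- rd(need("true"))
        mc <- mcnemar(a, b, tr)
        emit("acc_a=%.1f%% acc_b=%.1f%% n_a=%d n_b=%d mcnemar_p=%.4g",
             accuracy(a, tr), accuracy(b, tr), mc$n_a, mc$n_b, mc$p)
        0L
      },
      "run-all" = {
        dataset <- if (!is.null(fl("in"))) fl("in")
                   else synth_spec(seed = as.integer(fl("seed", "1")))
        cfg <- pipeline_config(
          dataset = dataset,
          feature_mode = fl("mode", "GPA"),
          classifier = fl("classifier", "GPC"),
          n_folds = as.integer(fl("folds", "10")),
          n_reshuffles = as.integer(fl("reshuffles", "10")),
          out_dir = need("out"),
          seed = as.integer(fl("seed", "1")))
        rep <- run_pipeline(cfg)
        emit("run-all: mean accuracy %.1f%%",
             mean(rep$crosstest$metrics$acc))
        0L
      },
      {
        message("unknown command: ", cmd)
        message(cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  emit("[%s] finished in %.1fs with exit code %d", cmd,
       as.numeric(difftime(Sys.time(), t0, units = "secs")), code)
  invisible(code)
}
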