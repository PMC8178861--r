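#' Pipeline run configuration
#'
#' Either point `corpus` at existing inputs (directories/files read by the
#' corpus readers) or leave it `NULL` to simulate a cohort with
#' [simulate_cohort()].
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param characteristics clinical speech characteristics to analyse.
#' @param alpha Spearman screening level.
#' @param cutoff EFA loading cutoff.
#' @param pa_iter,pa_percentile parallel-analysis settings.
#' @param simulate cohort configuration for simulated runs
#'   ([cohort_config()]).
#' @param with_audio simulate/analyse waveforms (slower; adds spectral
#'   features).
#' @param corpus optional list with `transcripts` (list), `labels`
#'   (data frame), `ratings` (`rating_panel`), and optional `audios`,
#'   `norms`, `embeddings`, `lexicon`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       characteristics = CHARACTERISTICS,
                       alpha = 0.05, cutoff = 0.6,
                       pa_iter = 100L, pa_percentile = 95,
                       simulate = cohort_config(), with_audio = TRUE,
                       corpus = NULL) {
  if (!length(characteristics)) stop("characteristics must be non-empty")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]
#' (`out_dir`, `seed`, `characteristics`, `alpha`, `cutoff`, `pa_iter`,
#' `pa_percentile`, `with_audio`) plus an optional `simulate:` block of
#' [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(cohort_config, y$simulate)
         else cohort_config()
  args <- y[intersect(names(y), c("out_dir", "seed", "characteristics",
                                  "alpha", "cutoff", "pa_iter",
                                  "pa_percentile", "with_audio"))]
  args$simulate <- sim
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load the corpus; extract the feature matrix; build
#' modal consensus ratings and inter-rater ICC per characteristic; screen
#' features against consensus by Spearman correlation; compute odds ratios
#' of impairment for every group pair; run EFA on the selected variables.
#' All intermediates are plain CSV/JSON under `out_dir`; reruns with the
#' same inputs and seed are byte-identical (the human-readable `run.log`
#' carries timestamps, the machine summary does not).
#'
#' @param cfg a [run_config()].
#' @return the run summary (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(stage, ...) {
    msg <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stage, paste0(...))
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    logmsg(name, "start")
    tryCatch(expr, error = function(e) {
      logmsg(name, "FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  corpus <- stage("corpus", {
    if (is.null(cfg$corpus)) {
      sim <- simulate_cohort(cfg$simulate, seed = cfg$seed)
      panel <- simulate_rating_panel(
        sim$true_severities[, cfg$characteristics, drop = FALSE],
        n_raters = cfg$simulate$n_raters, rater_sd = cfg$simulate$rater_sd,
        seed = cfg$seed + 1000L,
        rater_bias_sd = cfg$simulate$rater_bias_sd)
      audios <- NULL
      if (isTRUE(cfg$with_audio)) {
        audios <- lapply(seq_along(sim$transcripts), function(i) {
          simulate_waveform(sim$transcripts[[i]],
                            rate = cfg$simulate$sample_rate,
                            seed = cfg$seed + 2000L + i)
        })
        names(audios) <- names(sim$transcripts)
      }
      utils::write.csv(cbind(data.frame(sample_id = rownames(sim$true_severities)),
                             as.data.frame(sim$true_severities)),
                       file.path(cfg$out_dir, "true_severities.csv"),
                       row.names = FALSE)
      list(transcripts = sim$transcripts, labels = sim$labels,
           ratings = panel, audios = audios,
           norms = synthetic_norms(),
           embeddings = synthetic_embeddings(),
           lexicon = read_content_lexicon())
    } else cfg$corpus
  })
  utils::write.csv(corpus$labels, file.path(cfg$out_dir, "labels.csv"),
                   row.names = FALSE)

  features <- stage("extract", {
    if (is.null(corpus$embeddings) || is.null(corpus$lexicon)) {
      stop("picture_similarity needs word embeddings and a content lexicon; ",
           "supply both in the corpus (or run with a simulated corpus)")
    }
    fm <- extract_feature_matrix(corpus$transcripts, audios = corpus$audios,
                                 norms = corpus$norms, emb = corpus$embeddings,
                                 lexicon = corpus$lexicon)
    utils::write.csv(cbind(sample_id = rownames(fm), fm),
                     file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
    write_feature_manifest(file.path(cfg$out_dir, "feature_manifest.tsv"))
    fm
  })

  summary <- list(seed = cfg$seed, n_samples = nrow(features),
                  n_features = ncol(features), characteristics = list())
  group_pairs <- list(c("AD", "HC"), c("MCI", "HC"), c("AD", "MCI"))

  for (ch in cfg$characteristics) {
    cons <- stage(paste0("consensus:", ch), {
      cr <- consensus_rating(corpus$ratings, characteristic = ch)
      utils::write.csv(data.frame(sample_id = cr$item, characteristic = ch,
                                  consensus = cr$consensus,
                                  flagged = cr$flagged),
                       file.path(cfg$out_dir, paste0("consensus_", ch, ".csv")),
                       row.names = FALSE)
      cr
    })
    icc_res <- stage(paste0("icc:", ch), icc(corpus$ratings, characteristic = ch))
    screen <- stage(paste0("screen:", ch), {
      sc <- spearman_screen(features,
                            stats::setNames(cons$consensus, cons$item),
                            alpha = cfg$alpha)
      utils::write.csv(sc, file.path(cfg$out_dir, paste0("screen_", ch, ".csv")),
                       row.names = FALSE)
      sc
    })
    ors <- stage(paste0("odds:", ch), {
      res <- lapply(group_pairs, function(pr) {
        o <- group_odds_ratio(cons, corpus$labels, pr[1], pr[2])
        data.frame(characteristic = ch, groupA = pr[1], groupB = pr[2],
                   a = o$table[1, 1], b = o$table[1, 2],
                   c = o$table[2, 1], d = o$table[2, 2],
                   or = o$or_estimate, lo = o$ci95[1], hi = o$ci95[2],
                   corrected = o$corrected, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, res)
      utils::write.csv(df, file.path(cfg$out_dir, paste0("odds_", ch, ".csv")),
                       row.names = FALSE)
      df
    })
    selected <- screen$feature[screen$selected]
    efa_res <- stage(paste0("efa:", ch), {
      if (length(selected) < 2L) {
        logmsg(paste0("efa:", ch), "fewer than 2 selected variables; skipped")
        NULL
      } else {
        er <- run_efa(features[, selected, drop = FALSE], cutoff = cfg$cutoff,
                      n_iter = cfg$pa_iter, percentile = cfg$pa_percentile,
                      seed = cfg$seed)
        write_efa_report(er, screen,
                         file.path(cfg$out_dir, paste0("efa_", ch, ".csv")),
                         cutoff = cfg$cutoff)
        er
      }
    })
    summary$characteristics[[ch]] <- list(
      icc_single = icc_res$icc_single,
      icc_average = icc_res$icc_average,
      icc_band = icc_res$band,
      icc_p = icc_res$p_value,
      n_selected = length(selected),
      k_factors = if (is.null(efa_res)) NA_integer_ else efa_res$k,
      var_prop = if (is.null(efa_res)) numeric(0) else efa_res$var_prop,
      odds_ratios = stats::setNames(ors$or,
                                    paste0(ors$groupA, "_vs_", ors$groupB)))
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done", "summary written")
  invisible(summary)
}

# Tables-3/4-style report: variable, family, rho, then F1..Fk pattern
# loadings blanked below the cutoff, followed by a summary block.
write_efa_report <- function(efa_res, screen, path, cutoff = 0.6) {
  man <- feature_manifest()
  fam <- stats::setNames(man$family, man$name)
  vars <- efa_res$variables
  rho <- stats::setNames(screen$rho, screen$feature)[vars]
  df <- data.frame(variable = vars,
                   family = unname(fam[vars]),
                   rho = round(unname(rho), 3),
                   stringsAsFactors = FALSE)
  if (efa_res$k > 0L) {
    for (j in seq_len(efa_res$k)) {
      col <- ifelse(abs(efa_res$pattern[, j]) >= cutoff &
                      efa_res$assignments == j,
                    sprintf("%.2f", efa_res$pattern[, j]), "")
      df[[paste0("F", j)]] <- col
    }
  }
  df <- df[order(-abs(df$rho)), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  writeLines("", con)
  writeLines(paste0("# k_factors,", efa_res$k), con)
  if (efa_res$k > 0L) {
    writeLines(paste0("# variance_percent,",
                      paste(sprintf("%.1f", efa_res$var_prop), collapse = ",")),
               con)
    writeLines(paste0("# note,oblique factors: variance proportions are ",
                      "pattern sums of squares over p and need not sum to ",
                      "the total common variance"), con)
    if (efa_res$k > 1L) {
      for (j in seq_len(efa_res$k)) {
        writeLines(paste0("# phi_row_", j, ",",
                          paste(sprintf("%.3f", efa_res$phi[j, ]),
                                collapse = ",")), con)
      }
    }
  }
  invisible(path)
}
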