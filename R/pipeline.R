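# Stage-wise pipeline with file materialization between stages, so every
# stage is independently re-runnable, plus a checksum manifest.

#' Write / read a comment stream as CSV
#'
#' UTF-8 CSV with header `timestamp_s,text`, one file per video.
#'
#' @param stream A `comment_stream`.
#' @param path File path.
#' @param video_id,duration_s Stream metadata (not stored in the CSV).
#' @return `read_comments_csv` returns a `comment_stream`;
#'   `write_comments_csv` returns `path` invisibly.
#' @export
write_comments_csv <- function(stream, path) {
  stopifnot(inherits(stream, "comment_stream"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(stream$comments, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comments_csv
#' @export
read_comments_csv <- function(path, video_id, duration_s) {
  df <- read.csv(path, colClasses = c(timestamp_s = "numeric",
                                      text = "character"),
                 encoding = "UTF-8")
  comment_stream(video_id, duration_s, df)
}

#' Write / read a per-second trace as CSV (`second,value`)
#' @param x Numeric vector (one value per second).
#' @param path File path.
#' @return `read_trace_csv` returns a numeric vector.
#' @export
write_trace_csv <- function(x, path) {
  write.csv(data.frame(second = seq_along(x), value = as.numeric(x)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("second", "value") %in% names(df)))
    stop("trace file needs columns 'second' and 'value'")
  df$value[order(df$second)]
}

#' Write a score series (raw + z-scored) as CSV
#'
#' Header `video_id,second,raw_score,z_score`; `second` restarts per video.
#'
#' @param raw_list List of raw per-video `score_series`.
#' @param zseries The z-scored concatenated `score_series`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_score_series <- function(raw_list, zseries, path) {
  raw <- unlist(lapply(raw_list, `[[`, "score"), use.names = FALSE)
  vids <- zseries$videos
  df <- data.frame(
    video_id = rep(vids$video_id, vids$length),
    second = unlist(lapply(vids$length, seq_len), use.names = FALSE),
    raw_score = raw,
    z_score = zseries$score)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Controls an end-to-end run: either fully simulated inputs (the default)
#' or user-supplied files. All randomness derives from `seed`; the run
#' directory receives every intermediate product plus a checksum manifest.
#'
#' @param out_dir Run directory (created if missing).
#' @param seed Master seed recorded into every output.
#' @param sim A [sim_config()] (its seed is set from `seed`).
#' @param cv A [cv_config()] (its seed is set from `seed`).
#' @param smooth_width Odd moving-average width (s) applied to the raw
#'   danmaku series before z-scoring; 1 (default) applies no smoothing.
#' @param log10_power Use log10 band powers as features (default FALSE).
#' @param write_eeg Also materialize the simulated raw EEG as delimited
#'   matrices (large; default FALSE).
#' @param inputs Optional list for real data: `dictionary` (TSV path),
#'   `comments` (character vector of CSV paths), `durations` (integer
#'   vector, seconds per video), optional `features` (group feature CSV) and
#'   `selfreport` (trace CSV). When `features` is omitted the run is
#'   simulation-only for the EEG side.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = sim_config(),
                            cv = cv_config(n_repeats = 100L),
                            smooth_width = 1L,
                            log10_power = FALSE,
                            write_eeg = FALSE,
                            inputs = NULL) {
  sim$seed <- as.integer(seed)
  cv$seed <- as.integer(seed) + 1L
  if (!is.null(inputs)) {
    paths <- c(inputs$dictionary, inputs$comments, inputs$features,
               inputs$selfreport)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
    if (is.null(inputs$durations) ||
        length(inputs$durations) != length(inputs$comments))
      stop("inputs$durations must give one duration per comments file")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 cv = cv, smooth_width = as.integer(smooth_width),
                 log10_power = log10_power, write_eeg = write_eeg,
                 inputs = inputs),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full decoding pipeline
#'
#' Executes score -> features -> group average -> decode, materializing
#' every stage's output under the run directory: the dictionary, comment
#' streams, latent trajectory (simulation only), raw and z-scored score
#' series, self-report traces and their comparison, the group feature
#' matrix, the decoding report (per-fold metrics, aggregate summary,
#' coefficient map) and the univariate correlation map, plus a manifest
#' with the configuration echo and an md5 checksum of every file. Reruns
#' with the same configuration and seed are bit-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `pipeline_run`: list with the in-memory stage
#'   products (`scores`, `features`, `decoding`, `cor_map`,
#'   `selfreport_comparison`) and `files` (named paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(cfg$out_dir, ...)
  files <- character(0)
  add <- function(path) { files[length(files) + 1L] <<- path; path }
  simulated <- is.null(cfg$inputs)

  dict <- run_stage("dictionary", {
    d <- if (simulated) synthetic_dictionary()
         else read_dictionary(cfg$inputs$dictionary)
    write_dictionary(d, add(fp("dictionary.tsv")))
    d
  })

  latent <- NULL
  streams <- run_stage("comments", {
    if (simulated) {
      latent <- gen_latent(cfg$sim)
      write_trace_csv(latent$values, add(fp("latent.csv")))
      ss <- gen_comments(latent, dict, cfg$sim)
      for (s in ss)
        write_comments_csv(s, add(fp(paste0("comments_", s$video_id, ".csv"))))
      ss
    } else {
      Map(function(path, dur, i)
            read_comments_csv(path, paste0("video", i), dur),
          cfg$inputs$comments, cfg$inputs$durations,
          seq_along(cfg$inputs$comments))
    }
  })

  scores <- run_stage("score", {
    raw <- lapply(streams, score_seconds, dict = dict)
    if (cfg$smooth_width > 1L)
      raw <- lapply(raw, smooth_score_series, width_s = cfg$smooth_width)
    z <- zscore_across_videos(raw)
    write_score_series(raw, z, add(fp("scores.csv")))
    list(raw = raw, z = z)
  })

  sr_cmp <- run_stage("selfreport", {
    if (simulated) {
      sr <- gen_selfreport(latent, cfg$sim)
      write_trace_csv(sr$mean_trace, add(fp("selfreport_mean.csv")))
      compare_with_selfreport(scores$z, sr$mean_trace)
    } else if (!is.null(cfg$inputs$selfreport)) {
      compare_with_selfreport(scores$z, read_trace_csv(cfg$inputs$selfreport))
    } else NULL
  })

  features <- run_stage("features", {
    if (simulated) {
      if (cfg$write_eeg) {
        recs <- gen_eeg(latent, cfg$sim)
        for (r in recs)
          write_eeg_delim(r,
            add(fp(sprintf("eeg_%s_%s.csv", r$participant_id, r$video_id))),
            add(fp(sprintf("eeg_%s_%s.json", r$participant_id, r$video_id))))
      }
      fm <- simulate_group_features(latent, cfg$sim,
                                    log10_power = cfg$log10_power)
    } else if (!is.null(cfg$inputs$features)) {
      fm <- read_feature_matrix(cfg$inputs$features)
    } else {
      stop("no feature source: supply inputs$features or run simulated")
    }
    if (nrow(fm) != length(scores$z$score))
      stop("feature rows (", nrow(fm), ") do not align with score seconds (",
           length(scores$z$score), ")")
    write_feature_matrix(fm, add(fp("features_group.csv")))
    fm
  })

  decoding <- run_stage("decode", {
    res <- cross_validated_decode(features, scores$z, cfg$cv)
    write.csv(res$folds, add(fp("decoding_folds.csv")), row.names = FALSE)
    jsonlite::write_json(c(list(seed = cfg$seed), res$summary),
                         add(fp("decoding_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    write_coefficient_map(res, add(fp("coefficient_map.csv")))
    res
  })

  cor_map <- run_stage("correlation_map", {
    cm <- correlation_map(features, scores$z)
    write.csv(cm, add(fp("correlation_map.csv")), row.names = FALSE)
    cm
  })

  run_stage("manifest", {
    sums <- tools::md5sum(files)
    manifest <- list(
      seed = cfg$seed,
      simulated = simulated,
      smooth_width = cfg$smooth_width,
      log10_power = cfg$log10_power,
      cv = cfg$cv[c("n_folds", "n_repeats", "inner_folds", "seed")],
      sim = if (simulated)
        cfg$sim[c("n_participants", "fs", "video_durations_s",
                  "comment_rate", "seed")],
      files = lapply(seq_along(files), function(i)
        list(path = basename(files[i]), md5 = unname(sums[i]))))
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  structure(list(scores = scores, features = features, decoding = decoding,
                 cor_map = cor_map, selfreport_comparison = sr_cmp,
                 files = c(files, fp("manifest.json")), out_dir = cfg$out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", x$out_dir, "\n", sep = "")
  s <- x$decoding$summary
  cat(sprintf("  decoding r = %.3f +/- %.3f, NMSE = %.3f +/- %.3f\n",
              s$mean_r, s$sd_r, s$mean_nmse, s$sd_nmse))
  if (!is.null(x$selfreport_comparison))
    cat(sprintf("  danmaku vs self-report r = %.3f (p = %.3g)\n",
                x$selfreport_comparison$r, x$selfreport_comparison$p))
  cat(sprintf("  %d significant features in the Bonferroni map\n",
              sum(x$cor_map$significant)))
  invisible(x)
}

#' Write a full simulated fixture set to a directory
#'
#' Materializes dictionary TSV, per-video comment CSVs, ground-truth latent
#' CSV, self-report trace CSVs and (optionally) the raw EEG as delimited
#' matrices with JSON sidecars.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param write_eeg Write raw EEG matrices too (default FALSE; large).
#' @return Invisible character vector of written paths.
#' @export
simulate_dataset <- function(cfg, out_dir, write_eeg = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  paths <- character(0)
  dict <- synthetic_dictionary()
  paths <- c(paths, write_dictionary(dict, fp("dictionary.tsv")))
  latent <- gen_latent(cfg)
  paths <- c(paths, write_trace_csv(latent$values, fp("latent.csv")))
  for (s in gen_comments(latent, dict, cfg))
    paths <- c(paths,
               write_comments_csv(s, fp(paste0("comments_", s$video_id, ".csv"))))
  sr <- gen_selfreport(latent, cfg)
  paths <- c(paths, write_trace_csv(sr$mean_trace, fp("selfreport_mean.csv")))
  for (r in seq_len(ncol(sr$traces)))
    paths <- c(paths,
               write_trace_csv(sr$traces[, r], fp(sprintf("selfreport_rater%d.csv", r))))
  if (write_eeg) {
    for (rec in gen_eeg(latent, cfg)) {
      dpath <- fp(sprintf("eeg_%s_%s.csv", rec$participant_id, rec$video_id))
      mpath <- fp(sprintf("eeg_%s_%s.json", rec$participant_id, rec$video_id))
      write_eeg_delim(rec, dpath, mpath)
      paths <- c(paths, dpath, mpath)
    }
  }
  invisible(paths)
}
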