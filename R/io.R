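# Event-table IO (CSV/TSV, minimal FCS 3.x), run configuration, and the
# pipeline composing deconvolution, enrichment and panel statistics.

RESERVED_COLUMNS <- c("event_id", "population", "condition", "replicate")
CONDITIONS <- c("pre", "post", "control")

#' Channel columns of an event table
#'
#' Every column that is not part of the fixed schema (`event_id`,
#' `population`, `condition`, `replicate`) and not a `latent_*` column is a
#' fluorescence channel.
#'
#' @param table an event table (data frame).
#' @return Character vector of channel column names.
#' @export
event_channels <- function(table) {
  setdiff(names(table)[!startsWith(names(table), "latent_")],
          RESERVED_COLUMNS)
}

validate_event_table <- function(df, path = "<in-memory>") {
  missing <- setdiff(RESERVED_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("event table `%s` is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ch <- event_channels(df)
  if (length(ch) == 0L) {
    stop(sprintf("event table `%s` has no channel column", path),
         call. = FALSE)
  }
  for (cc in ch) {
    if (!is.numeric(df[[cc]])) {
      stop(sprintf("channel column `%s` in `%s` is not numeric", cc, path),
           call. = FALSE)
    }
  }
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown condition label(s) in `%s`: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$event_id)) {
    stop(sprintf("event_id is not unique in `%s`", path), call. = FALSE)
  }
  n_neg <- sum(vapply(ch, function(cc) sum(df[[cc]] < 0), numeric(1)))
  if (n_neg > 0L) {
    warning(sprintf(paste0("%d negative intensity value(s) in `%s` ",
                           "(possible baseline subtraction); retained, ",
                           "not dropped"), n_neg, path), call. = FALSE)
    attr(df, "negative_flagged") <- n_neg
  }
  new_event_table(df, channel = ch)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", txt = "tsv", fcs = "fcs",
         stop(sprintf("cannot guess the format of `%s`", path),
              call. = FALSE))
}

#' Read an event table
#'
#' Reads per-event fluorescence data from CSV/TSV (canonical interchange,
#' schema: `event_id`, channel columns, optional `latent_*`, `population`,
#' `condition`, `replicate`) or from an FCS 3.x file (channels mapped to
#' table columns via `channels`; schema columns filled from the remaining
#' arguments).  Negative intensities are flagged with a warning but never
#' dropped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"fcs"`.
#' @param channels for FCS: named character vector mapping output column
#'   names to FCS `$PnN` channel names, e.g. `c(FL1 = "FITC-A")`; `NULL`
#'   keeps all FCS channels under their own names.
#' @param population,condition,replicate labels used when the source (FCS)
#'   does not carry them.
#' @return A validated `event_table`.
#' @export
read_events <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        channels = NULL, population = "pop",
                        condition = "pre", replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: `%s`", path),
                               call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (format == "fcs") {
    mat <- read_fcs(path, channels = channels)
    df <- data.frame(event_id = seq_len(nrow(mat)))
    df <- cbind(df, as.data.frame(mat))
    df$population <- population
    df$condition <- condition
    df$replicate <- replicate
  } else {
    df <- utils::read.csv(path, sep = if (format == "csv") "," else "\t",
                          stringsAsFactors = FALSE)
  }
  validate_event_table(df, path = path)
}

#' Write an event table to CSV/TSV
#'
#' @param table an event table.
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  utils::write.table(as.data.frame(table), path,
                     sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal FCS 3.x reader -------------------------------------------------
# Reads the HEADER offsets, parses the delimited TEXT segment, and decodes a
# float (F, 32-bit) or double (D, 64-bit) DATA segment in either byte order.
# Integer data and analysis segments are out of scope.
parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter produces an empty last element; drop it
  if (length(parts) %% 2L == 1L && parts[length(parts)] == "") {
    parts <- parts[-length(parts)]
  }
  if (length(parts) %% 2L == 1L) {
    stop("malformed FCS TEXT segment (odd keyword/value count)",
         call. = FALSE)
  }
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

#' Read the event matrix of an FCS 3.x file
#'
#' Minimal reader for the standard keyword/channel layout: `$DATATYPE` F or
#' D, `$MODE` L, any `$BYTEORD`.
#'
#' @inheritParams read_events
#' @return Numeric matrix, one row per event, channels as columns.
#' @export
read_fcs <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!startsWith(version, "FCS3")) {
    stop(sprintf("unsupported FCS version `%s` in `%s`", version, path),
         call. = FALSE)
  }
  off <- as.numeric(c(substr(header, 11, 18), substr(header, 19, 26),
                      substr(header, 27, 34), substr(header, 35, 42)))
  seek(con, off[1])
  kw <- parse_fcs_text(readBin(con, "raw", off[2] - off[1] + 1))
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D")) {
    stop(sprintf("unsupported FCS $DATATYPE `%s` (only F/D)", dtype),
         call. = FALSE)
  }
  size <- if (dtype == "F") 4L else 8L
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  data_beg <- off[3]
  data_end <- off[4]
  if (data_beg == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_beg <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  seek(con, data_beg)
  vals <- readBin(con, "numeric", n = npar * ntot, size = size,
                  endian = endian)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  fcs_names <- vapply(seq_len(npar), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1))
  colnames(mat) <- fcs_names
  if (!is.null(channels)) {
    missing <- setdiff(unname(channels), fcs_names)
    if (length(missing) > 0L) {
      stop(sprintf("unmappable FCS channel(s) in `%s`: %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    mat <- mat[, unname(channels), drop = FALSE]
    colnames(mat) <- names(channels)
  }
  mat
}

# --- run configuration ------------------------------------------------------

#' Pipeline run configuration
#'
#' @param inputs named list of event tables, or named character vector of
#'   file paths (read with [read_events()]).
#' @param control label of the non-fluorescent control population.
#' @param channel channel column analyzed.
#' @param threshold outlier threshold on the normalized reference scale.
#' @param reference value the control mean maps to under normalization
#'   (instrument-scale convention).
#' @param gates sorting-gate means `c(low =, high =)` (A.U., ordered).
#' @param seed top-level integer seed.
#' @param out optional output directory for JSON/CSV reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs, control, channel = "FL1", threshold = 1250,
                       reference = 1, gates = c(low = 4.1, high = 779.5),
                       seed = 1L, out = NULL) {
  stopifnot(length(gates) == 2L)
  if (is.null(names(gates))) names(gates) <- c("low", "high")
  if (gates[["high"]] <= gates[["low"]]) {
    stop("gates must be ordered: high > low", call. = FALSE)
  }
  structure(list(inputs = inputs, control = control, channel = channel,
                 threshold = threshold, reference = reference,
                 gates = gates, seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Read a pipeline configuration from YAML/JSON
#'
#' The document mirrors [run_config()] field-for-field (`inputs` as a named
#' map of file paths).
#'
#' @param path YAML or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  gates <- unlist(cfg$gates)
  run_config(inputs = unlist(cfg$inputs), control = cfg$control,
             channel = cfg$channel %||% "FL1",
             threshold = cfg$threshold %||% 1250,
             reference = cfg$reference %||% 1,
             gates = if (is.null(gates)) c(low = 4.1, high = 779.5)
                     else gates,
             seed = cfg$seed %||% 1L, out = cfg$out)
}

#' Read a simulation scenario from YAML/JSON
#'
#' The document mirrors [scenario_config()]: a `seed`, optional
#' `default_n`, and a `populations` map whose entries carry `signal`
#' (`shape`, `scale`), `noise` (`family`, `mean`, `variance`), optional
#' `survival` (`p0`, `beta`) and optional `n`.
#'
#' @param path YAML or JSON file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pops <- lapply(cfg$populations, function(p) {
    out <- list(signal = signal_params(p$signal$shape, p$signal$scale),
                noise = noise_model(p$noise$family %||% "gamma",
                                    mean = p$noise$mean,
                                    variance = p$noise$variance %||% 0))
    if (!is.null(p$survival)) {
      out$survival <- survival_model(p$survival$p0, p$survival$beta)
    }
    if (!is.null(p[["n"]])) out$n <- p[["n"]]
    out
  })
  scenario_config(pops, seed = cfg$seed %||% 1L,
                  default_n = cfg$default_n %||% 30000L)
}

# --- pipeline ---------------------------------------------------------------

try_stage <- function(errors, population, stage, expr) {
  tryCatch(expr, error = function(e) {
    structure(list(population = population, stage = stage,
                   message = conditionMessage(e)), class = "stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' For every non-control population: moment summaries, Gamma deconvolution
#' against the control, and a re-convolution KS check.  For every
#' population with both `pre` and `post` events: the enrichment curve, the
#' inferred selection strength, and the gate survival-ratio prediction.
#' For the whole panel: per-replicate outlier percentages and CVs on the
#' control-normalized scale (and dual-reporter correlations where a table
#' carries two channels).  A stage error (e.g. a noise-dominated channel)
#' is recorded with its population and stage labels and the remaining
#' stages continue.  The run is deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @return A report bundle (class `flowdecon_report`): lists `populations`,
#'   `pairs`, `panel`, `errors`, and `meta` (seed, config hash, package
#'   version).  Write it with [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tables <- config$inputs
  if (is.character(tables)) {
    paths <- tables
    tables <- lapply(paths, read_events)
    names(tables) <- names(paths)
  }
  if (!config$control %in% names(tables)) {
    stop(sprintf("control population `%s` not among inputs (%s)",
                 config$control, paste(names(tables), collapse = ", ")),
         call. = FALSE)
  }
  ch <- config$channel
  control_events <- extract_channel(tables[[config$control]], ch)
  control_mean <- mean(control_events)
  errors <- list()
  note_error <- function(e) errors[[length(errors) + 1L]] <<- e

  pops <- list()
  fits <- list()
  for (lab in setdiff(names(tables), config$control)) {
    tab <- tables[[lab]]
    for (cond in intersect(unique(tab$condition), c("pre", "post"))) {
      # pre events of table "x" -> key "x"; post events (whether in the
      # same table or a companion table "x_post") -> key "x:post"
      base <- sub("_post$", "", lab)
      key <- if (cond == "pre") base else paste0(base, ":post")
      sub <- tab[tab$condition == cond, , drop = FALSE]
      res <- try_stage(errors, key, "deconvolve", {
        fit <- deconvolve(extract_channel(sub, ch), control_events,
                          channel = ch)
        d_seed <- derive_seed(config$seed, paste0(key, ":reconvolve"))
        rc <- reconvolve(fit, seed = d_seed)
        rep_ <- validate_reconvolution(fit$raw, rc, seed = d_seed)
        list(n = fit$n,
             raw_moments = unclass(fit$raw_moments)[c("n", "mean",
                                                      "variance")],
             noise_moments = unclass(fit$noise_moments)[c("n", "mean",
                                                          "variance")],
             signal = list(shape = fit$signal$shape,
                           scale = fit$signal$scale,
                           mean = unname(fit$signal_moments[["mean"]]),
                           variance =
                             unname(fit$signal_moments[["variance"]])),
             reconvolution = list(D = rep_$D, location = rep_$location,
                                  seed = d_seed),
             fit = fit)
      })
      if (inherits(res, "stage_error")) note_error(unclass(res))
      else {
        fits[[key]] <- res$fit
        res$fit <- NULL
        pops[[key]] <- res
      }
    }
  }

  pairs <- list()
  for (lab in unique(sub("_post$", "",
                         setdiff(names(tables), config$control)))) {
    pre_key <- lab; post_key <- paste0(lab, ":post")
    if (!is.null(fits[[pre_key]]) && !is.null(fits[[post_key]])) {
      res <- try_stage(errors, lab, "enrichment", {
        em <- enrichment_model(fits[[pre_key]], fits[[post_key]],
                               labels = c(pre_key, post_key))
        cv <- enrichment_curve(em)
        gs <- predict_gate_survival(em, gates = config$gates)
        list(f_b = coef(fits[[pre_key]]), f_a = coef(fits[[post_key]]),
             log_ef_slope = cv$slope, log_ef_intercept = cv$intercept,
             shape_mismatch = gs$shape_mismatch, beta = gs$beta,
             gates = as.list(config$gates), survival_ratio = gs$ratio)
      })
      if (inherits(res, "stage_error")) note_error(unclass(res))
      else pairs[[lab]] <- res
    }
  }

  panel <- try_stage(errors, "<panel>", "panel_statistics", {
    panel_statistics(tables[setdiff(names(tables), config$control)],
                     control_mean = control_mean,
                     threshold = config$threshold,
                     reference = config$reference, channel = ch)
  })
  if (inherits(panel, "stage_error")) {
    note_error(unclass(panel)); panel <- NULL
  }

  correlations <- list()
  for (lab in setdiff(names(tables), config$control)) {
    chs <- event_channels(tables[[lab]])
    if (length(chs) >= 2L) {
      res <- try_stage(errors, lab, "dual_reporter_correlation", {
        dual_reporter_correlation(tables[[lab]][[chs[1]]],
                                  tables[[lab]][[chs[2]]])
      })
      if (inherits(res, "stage_error")) note_error(unclass(res))
      else correlations[[lab]] <- res
    }
  }

  cfg_digest <- hash31(paste(
    deparse(unclass(config)[c("control", "channel", "threshold",
                              "reference", "gates", "seed")]),
    collapse = ""))
  structure(list(populations = pops, pairs = pairs, panel = panel,
                 correlations = correlations, errors = errors,
                 meta = list(seed = config$seed,
                             control = config$control,
                             control_mean = control_mean,
                             config_hash = cfg_digest,
                             version =
                               as.character(utils::packageVersion(
                                 "flowdecon")))),
            class = "flowdecon_report")
}

#' @export
print.flowdecon_report <- function(x, ...) {
  cat(sprintf("flowdecon report: %d population fit(s), %d pre/post pair(s)\n",
              length(x$populations), length(x$pairs)))
  for (lab in names(x$populations)) {
    p <- x$populations[[lab]]
    cat(sprintf("  %-12s k = %.4g, theta = %.4g, reconvolution D = %.4f\n",
                lab, p$signal$shape, p$signal$scale, p$reconvolution$D))
  }
  for (lab in names(x$pairs)) {
    pr <- x$pairs[[lab]]
    cat(sprintf("  %-12s beta = %.4g per A.U., gate survival ratio = %.4g\n",
                paste0(lab, " pair"), pr$beta, pr$survival_ratio))
  }
  if (length(x$errors) > 0L) {
    cat(sprintf("  %d stage error(s):\n", length(x$errors)))
    for (e in x$errors) {
      cat(sprintf("    [%s/%s] %s\n", e$population, e$stage, e$message))
    }
  }
  invisible(x)
}

#' Write a report bundle as JSON (and the panel table as CSV)
#'
#' JSON output is deterministic for a fixed seed: rerunning the pipeline
#' with the same configuration yields byte-identical files.
#'
#' @param report a `flowdecon_report` from [run_pipeline()].
#' @param path output JSON path; the per-replicate panel table is written
#'   alongside with suffix `_panel.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "flowdecon_report"))
  out <- unclass(report)
  panel <- out$panel
  out$panel <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(panel)) {
    utils::write.csv(panel, sub("\\.json$", "_panel.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
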