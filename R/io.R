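#' Read and write CEE data tables
#'
#' Plain-text comma-separated tables with a header row, UTF-8, `.` decimal.
#' Schemas (also documented in `inst/extdata/formats.md`):
#' * track: `time_s`, `x_m`, `y_m` — strictly increasing times, finite
#'   coordinates;
#' * blocks: `block`, `phase`, `value`, `observed` — one row per block,
#'   `value` empty iff `observed` is 0;
#' * pings: `time_s`, `range_m`, `spl_db`, `sel_db`, `transmitted` —
#'   strictly increasing times.
#'
#' Readers validate strictly: a missing column fails, an unknown column
#' warns, malformed cells fail with row context. Writers round-trip at full
#' precision.
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return the validated typed data.frame (`"cee_track"`,
#'   `"cee_blocks"`, `"cee_pings"`); writers return `path` invisibly.
#' @name cee_io
NULL

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file '%s' lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s file '%s' has unknown column(s): %s", what, path,
                    paste(extra, collapse = ", ")))
  df[required]
}

check_numeric <- function(df, cols, what, path) {
  for (cl in cols) {
    bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad))
      stop(sprintf("%s file '%s': non-numeric value in column '%s', row %d",
                   what, path, cl, bad[1]))
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df
}

#' @rdname cee_io
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = "character")
  df <- check_columns(df, c("time_s", "x_m", "y_m"), "track", path)
  df <- check_numeric(df, names(df), "track", path)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("track file '%s': time_s not strictly increasing at row %d",
                 path, bad[1] + 1L))
  if (any(!is.finite(df$x_m)) || any(!is.finite(df$y_m)))
    stop(sprintf("track file '%s': non-finite coordinates", path))
  structure(df, class = c("cee_track", "data.frame"))
}

#' @rdname cee_io
#' @export
write_track <- function(x, path) {
  write.csv(as.data.frame(x)[c("time_s", "x_m", "y_m")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cee_io
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = "character")
  df <- check_columns(df, c("block", "phase", "value", "observed"),
                      "blocks", path)
  df$value[df$value == ""] <- NA
  df <- check_numeric(df, c("block", "value", "observed"), "blocks", path)
  df$block <- as.integer(df$block)
  df$observed <- df$observed != 0
  df$phase <- factor(df$phase, levels = c("pre", "exposure", "post"))
  if (anyNA(df$phase)) stop(sprintf("blocks file '%s': invalid phase label", path))
  bad <- which(df$observed != !is.na(df$value))
  if (length(bad))
    stop(sprintf("blocks file '%s': value present iff observed violated at row %d",
                 path, bad[1]))
  structure(df, class = c("cee_blocks", "data.frame"))
}

#' @rdname cee_io
#' @export
write_blocks <- function(x, path) {
  df <- as.data.frame(x)[c("block", "phase", "value", "observed")]
  df$observed <- as.integer(df$observed)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname cee_io
#' @export
read_pings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = "character")
  df <- check_columns(df, c("time_s", "range_m", "spl_db", "sel_db",
                            "transmitted"), "pings", path)
  df <- check_numeric(df, names(df), "pings", path)
  df$transmitted <- df$transmitted != 0
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("pings file '%s': time_s not strictly increasing at row %d",
                 path, bad[1] + 1L))
  structure(df, class = c("cee_pings", "data.frame"))
}

#' @rdname cee_io
#' @export
write_pings <- function(x, path) {
  df <- as.data.frame(x)[c("time_s", "range_m", "spl_db", "sel_db",
                           "transmitted")]
  df$transmitted <- as.integer(df$transmitted)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-CEE result to JSON
#'
#' Serialises a [analyze_cee()] result (per-metric phase means, response and
#' persistence probabilities, detection flags, PSRF, acoustic summaries and
#' MCMC configuration) at full precision.
#'
#' @param result A `"cee_result"`.
#' @param path Output path.
#' @export
write_cee_result <- function(result, path) {
  payload <- list(cee_id = attr(result, "cee_id"),
                  metrics = as.data.frame(result),
                  rl_max_db = attr(result, "rl_max_db"),
                  csel_db = attr(result, "csel_db"),
                  v1_kmh = attr(result, "v1_kmh"),
                  mcmc = attr(result, "mcmc"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Detection counts and percentage
#'
#' Summarises detection flags as `k` detections of `n` CEEs and a percentage
#' rounded to one decimal, the footer convention of response-summary tables
#' (e.g. 5 of 8 gives `62.5`).
#'
#' @param flags Logical vector, non-empty (one per CEE with the metric
#'   available).
#' @return List with `k`, `n`, `pct`.
#' @examples
#' detection_proportion(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' @export
detection_proportion <- function(flags) {
  if (length(flags) == 0) stop("flags must be non-empty")
  if (anyNA(flags)) stop("flags must not contain NA")
  k <- sum(flags)
  n <- length(flags)
  list(k = k, n = n, pct = round(100 * k / n, 1))
}

#' Build a response-summary table across CEEs
#'
#' Assembles per-CEE, per-metric rows (phase means with sd, response and
#' persistence probabilities, detection flags) and footer rows giving
#' detections/total and percentage per CEE type, metric and phase comparison.
#' A CEE whose manifest availability flag for a metric is `FALSE` is excluded
#' from that metric's rows and denominators.
#'
#' @param results Named list of `"cee_result"` objects (names = `cee_id`), or
#'   a single combined data.frame with a `cee_id` column.
#' @param manifest Data frame with columns `cee_id`, `cee_type` and logical
#'   availability flags `has_whistle`, `has_subgroup`, `has_movement`.
#' @return A list of class `"cee_summary"`: `rows` (per CEE x metric) and
#'   `footer` (`cee_type`, `metric`, `comparison`, `k`, `n`, `pct`).
#' @export
build_summary <- function(results, manifest) {
  req <- c("cee_id", "cee_type", "has_whistle", "has_subgroup", "has_movement")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(manifest$cee_id))
    stop("duplicate cee_id in manifest: ",
         manifest$cee_id[anyDuplicated(manifest$cee_id)])
  rows <- if (is.data.frame(results)) results else {
    if (anyDuplicated(names(results)))
      stop("duplicate cee_id in results: ",
           names(results)[anyDuplicated(names(results))])
    do.call(rbind, lapply(names(results), function(id) {
      df <- as.data.frame(results[[id]])
      df$cee_id <- id
      df
    }))
  }
  rows <- merge(rows, manifest[req], by = "cee_id", sort = FALSE)
  flag_col <- c(whistle = "has_whistle", subgroup = "has_subgroup",
                movement = "has_movement")
  keep <- mapply(function(m, i) rows[[flag_col[[m]]]][i],
                 rows$metric, seq_len(nrow(rows)))
  rows <- rows[keep, setdiff(names(rows), unname(flag_col))]

  footer <- do.call(rbind, lapply(split(rows, list(rows$cee_type, rows$metric),
                                        drop = TRUE), function(g) {
    rbind(
      data.frame(cee_type = g$cee_type[1], metric = g$metric[1],
                 comparison = "exposure_vs_pre",
                 as.data.frame(detection_proportion(g$detected_exposure))),
      data.frame(cee_type = g$cee_type[1], metric = g$metric[1],
                 comparison = "post_vs_pre",
                 as.data.frame(detection_proportion(g$detected_post)))
    )
  }))
  rownames(footer) <- NULL
  structure(list(rows = rows, footer = footer), class = "cee_summary")
}

#' @export
print.cee_summary <- function(x, ...) {
  cat(sprintf("CEE response summary: %d rows, %d CEEs\n",
              nrow(x$rows), length(unique(x$rows$cee_id))))
  cat("\nDetections / total (per cent):\n")
  f <- x$footer
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-8s %-9s %-16s %d/%d (%.1f%%)\n", f$cee_type[i],
                f$metric[i], f$comparison[i], f$k[i], f$n[i], f$pct[i]))
  invisible(x)
}
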