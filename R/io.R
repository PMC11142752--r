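#' @title Table and sequence I/O
#' @description Readers/writers for the plain-text formats the pipeline
#'   touches. All writers emit a fixed column order; readers validate types
#'   and report offending row numbers. Genomic coordinates are 0-based
#'   half-open internally; GTF-style interchange is 1-based inclusive (see
#'   [coords_to_internal()]).
#' @name io_formats
NULL

JUNCTION_COLS <- c("event_id", "sample_id", "inc_count", "skip_count")

#' Read a junction-count table
#'
#' @param path TSV with header columns `event_id`, `sample_id`, `inc_count`,
#'   `skip_count`.
#' @return data.frame of validated records (counts as non-negative integers).
#' @export
read_junction_counts <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = 1:2)))
  missing <- setdiff(JUNCTION_COLS, names(df))
  stop_if_not(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  df <- df[, JUNCTION_COLS]
  for (col in c("inc_count", "skip_count")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] != floor(df[[col]]))
    stop_if_not(length(bad) == 0, "invalid %s at row(s) %s", col,
                paste(head(bad, 5), collapse = ", "))
    df[[col]] <- as.integer(df[[col]])
  }
  dup <- which(duplicated(df[c("event_id", "sample_id")]))
  stop_if_not(length(dup) == 0, "duplicate (event, sample) pair at row(s) %s",
              paste(head(dup, 5), collapse = ", "))
  df
}

#' Write a junction-count table
#' @param df data.frame with the junction-count columns.
#' @param path output TSV path.
#' @export
write_junction_counts <- function(df, path) {
  data.table::fwrite(df[, JUNCTION_COLS], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a MISO-style PSI summary
#'
#' Tab-delimited with columns `event_name`, `miso_posterior_mean`, `ci_low`,
#' `ci_high`. Multi-isoform rows (comma-separated PSI values) are outside the
#' two-isoform model and skipped with a warning; the number skipped is
#' attached as attribute `n_skipped`.
#'
#' @param path file path.
#' @return data.frame with `event_id`, `psi`, `ci_low`, `ci_high`, `ci_width`.
#' @export
read_miso_summary <- function(path) {
  empty <- data.frame(event_id = character(), psi = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      ci_width = numeric())
  if (file.size(path) == 0) return(structure(empty, n_skipped = 0L))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("event_name", "miso_posterior_mean", "ci_low", "ci_high")
  missing <- setdiff(req, names(df))
  stop_if_not(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(structure(empty, n_skipped = 0L))
  multi <- grepl(",", df$miso_posterior_mean) | grepl(",", df$ci_low) |
    grepl(",", df$ci_high)
  if (any(multi)) warning(sprintf("skipped %d multi-isoform row(s)", sum(multi)))
  df <- df[!multi, , drop = FALSE]
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    stop_if_not(!anyNA(v), "unparseable %s field at row(s) %s", what,
                paste(head(which(is.na(v)), 5), collapse = ", "))
    v
  }
  out <- data.frame(event_id = df$event_name,
                    psi = num(df$miso_posterior_mean, "psi"),
                    ci_low = num(df$ci_low, "ci_low"),
                    ci_high = num(df$ci_high, "ci_high"))
  out$ci_width <- out$ci_high - out$ci_low
  structure(out, n_skipped = sum(multi))
}

#' Read an rMATS JC-format table
#'
#' Parses the junction-count dialect: comma-separated per-replicate counts in
#' `IJC_SAMPLE_1` / `SJC_SAMPLE_1` and effective lengths `IncFormLen` /
#' `SkipFormLen`, expanded to one record per replicate.
#'
#' @param path file path.
#' @return data.frame with `event_id`, `replicate`, `inc_count`,
#'   `skip_count`, `inc_eff_len`, `skip_eff_len`, plus `inc_level` if the
#'   rMATS `IncLevel1` column is present.
#' @export
read_rmats_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncFormLen", "SkipFormLen")
  missing <- setdiff(req, names(df))
  stop_if_not(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  stop_if_not(all(df$IncFormLen > 0) && all(df$SkipFormLen > 0),
              "effective length fields must be positive")
  id <- if ("ID" %in% names(df)) as.character(df$ID) else as.character(seq_len(nrow(df)))
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    inc <- as.integer(strsplit(as.character(df$IJC_SAMPLE_1[i]), ",")[[1]])
    skp <- as.integer(strsplit(as.character(df$SJC_SAMPLE_1[i]), ",")[[1]])
    stop_if_not(length(inc) == length(skp),
                "replicate count mismatch at row %d", i)
    rec <- data.frame(event_id = id[i], replicate = seq_along(inc),
                      inc_count = inc, skip_count = skp,
                      inc_eff_len = df$IncFormLen[i],
                      skip_eff_len = df$SkipFormLen[i])
    if ("IncLevel1" %in% names(df)) {
      rec$inc_level <- suppressWarnings(
        as.numeric(strsplit(as.character(df$IncLevel1[i]), ",")[[1]]))
    }
    rec
  }))
  rownames(out) <- NULL
  out
}

#' Write/read an event annotation table
#' @param events data.frame with `event_id`, `gene`, `event_type`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`, `inc_eff_len`, `skip_eff_len` (and
#'   optionally `role`). Coordinates 0-based half-open.
#' @param path TSV path.
#' @export
write_event_annotation <- function(events, path) {
  data.table::fwrite(events, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_event_annotation
#' @export
read_event_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("event_id", "event_type", "inc_eff_len", "skip_eff_len")
  missing <- setdiff(req, names(df))
  stop_if_not(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  bad <- which(!df$event_type %in% c("SE", "MXE", "A5SS", "A3SS", "RI"))
  stop_if_not(length(bad) == 0, "invalid event_type at row(s) %s",
              paste(head(bad, 5), collapse = ", "))
  stop_if_not(all(df$inc_eff_len > 0) && all(df$skip_eff_len > 0),
              "effective lengths must be positive")
  df
}

#' Generic TSV helpers with deterministic column order
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write a PsiMatrix
#'
#' `wide` form is events x samples with `NA` for undetected entries; `long`
#' form has one row per detected (event, sample) pair including the CI width.
#'
#' @param x a `PsiMatrix`.
#' @param path output TSV path.
#' @param form `"wide"` or `"long"`.
#' @export
write_psi_matrix <- function(x, path, form = c("wide", "long")) {
  form <- match.arg(form)
  if (form == "wide") {
    df <- data.frame(event_id = x$events, x$psi, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  } else {
    idx <- which(x$detected, arr.ind = TRUE)
    df <- data.frame(event_id = x$events[idx[, 1]],
                     sample_id = x$samples[idx[, 2]],
                     psi = x$psi[idx], ci_width = x$ci_width[idx])
    df <- df[order(df$event_id, df$sample_id), ]
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Convert between internal and GTF-style coordinates
#'
#' Internal convention: 0-based half-open `[start, end)`. GTF-style
#' interchange: 1-based inclusive `[start, end]`.
#'
#' @param start,end coordinate vectors.
#' @return data.frame with converted `start`, `end`.
#' @export
coords_to_internal <- function(start, end) {
  stop_if_not(all(start >= 1) && all(end >= start),
              "1-based inclusive coordinates require 1 <= start <= end")
  data.frame(start = start - 1L, end = end)
}

#' @rdname coords_to_internal
#' @export
coords_to_gtf <- function(start, end) {
  stop_if_not(all(start >= 0) && all(end > start),
              "0-based half-open coordinates require 0 <= start < end")
  data.frame(start = start + 1L, end = end)
}

#' Append a JSON-lines run manifest record
#'
#' Records the command, configuration hash, seed and package version so runs
#' can be reproduced from their outputs.
#'
#' @param path manifest file (created if absent; one JSON object per line).
#' @param command character command/subcommand name.
#' @param config named list of parameters (hashed into the record).
#' @param seed integer seed used.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA) {
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              command = command,
              config_hash = substr(paste(
                as.hexmode(utf8ToInt(substr(jsonlite::toJSON(
                  config, auto_unbox = TRUE), 1, 2048))), collapse = ""), 1, 40),
              seed = seed,
              version = as.character(packageVersion("spliceHet")))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  invisible(path)
}

#' Parse a simple key-value configuration file
#'
#' Accepts `key = value` or `key: value` lines (comments with `#`), or a
#' JSON object if the file starts with `{`. Values are parsed as numbers,
#' logicals, or comma-separated vectors where possible.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) && grepl("^\\s*\\{", txt[1])) {
    return(jsonlite::fromJSON(paste(txt, collapse = "\n")))
  }
  txt <- sub("#.*$", "", txt)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  out <- list()
  for (line in txt) {
    m <- regmatches(line, regexec("^([^=:]+)[=:](.*)$", line))[[1]]
    stop_if_not(length(m) == 3, "unparseable config line: %s", line)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(toupper(parts) %in% c("TRUE", "FALSE"))) as.logical(toupper(parts))
      else parts
  }
  out
}
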