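# Plain-text I/O used by the command-line interface: CSV with '#' metadata
# header lines, discrete trajectories as one integer per line, feature
# trajectories as CSV rows.

write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write a kinetic trace to CSV
#'
#' Columns `time,signal`; assay metadata (mode, allotype, DM concentration,
#' temperature) as `# key=value` header lines.
#'
#' @param trace a `kinetic_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  write_csv_meta(
    data.frame(time = trace$times, signal = trace$signal), path,
    meta = list(mode = trace$mode, allotype = trace$allotype,
                dm_conc = trace$dm_conc, temperature = trace$temperature)
  )
}

#' Read a kinetic trace from CSV
#'
#' @param path CSV path as written by [write_trace_csv()].
#' @return a `kinetic_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- read_csv_meta(path)
  m <- attr(df, "meta")
  structure(
    list(times = df$time, signal = df$signal,
         mode = m$mode %||% "dissociation",
         allotype = m$allotype %||% NA_character_,
         dm_conc = as.numeric(m$dm_conc %||% NA),
         temperature = as.numeric(m$temperature %||% NA)),
    class = "kinetic_trace"
  )
}

#' Write / read discrete trajectories (one integer per line, one file each)
#'
#' @param dtrajs a `dtraj_set` or list of integer vectors.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_dtrajs <- function(dtrajs, dir) {
  trajs <- if (inherits(dtrajs, "dtraj_set")) dtrajs$dtrajs else dtrajs
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("dtraj_%03d.txt", seq_along(trajs)))
  for (i in seq_along(trajs)) {
    writeLines(as.character(trajs[[i]]), paths[i])
  }
  invisible(paths)
}

#' @rdname write_dtrajs
#' @param paths files to read.
#' @export
read_dtrajs <- function(paths) {
  trajs <- lapply(paths, function(p) as.integer(readLines(p)))
  structure(list(dtrajs = trajs, n_states = max(unlist(trajs)), stride = 1),
            class = "dtraj_set")
}
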