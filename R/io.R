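#' Write a force trace to the package's TSV dialect
#'
#' Plain-text format: "#key=value" header lines (sampling_hz,
#' downsample_factor, mode, trap_stiffness_pN_per_nm, trap_separation_nm,
#' temperature_C, schema_version) followed by a tab-separated table with
#' columns \code{time_s}, \code{force_pN} and optionally
#' \code{extension_nm}, \code{truth_state}, \code{truth_bound}. Values are
#' written to 6 decimals; a write-read round trip is lossless to that
#' precision.
#'
#' @param trace an [ot_trace()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  hdr <- c(
    sprintf("#sampling_hz=%.6g", trace$sampling_hz),
    sprintf("#downsample_factor=%d", trace$downsample_factor),
    sprintf("#mode=%s", trace$mode),
    sprintf("#trap_stiffness_pN_per_nm=%.6g",
            if (!is.null(trace$model)) trace$model$trap_stiffness else NA),
    sprintf("#trap_separation_nm=%.6g", trace$trap_separation[1]),
    sprintf("#temperature_C=%.6g",
            if (!is.null(trace$model)) {
              (trace$model$kT / 0.0138065) - 273.15
            } else 25),
    "#schema_version=1")
  df <- data.frame(time_s = sprintf("%.6f", trace$time),
                   force_pN = sprintf("%.6f", trace$force))
  if (!is.null(trace$extension)) {
    df$extension_nm <- sprintf("%.6f", trace$extension)
  }
  if (!is.null(trace$truth_state)) df$truth_state <- trace$truth_state
  if (!is.null(trace$truth_bound)) {
    df$truth_bound <- as.integer(trace$truth_bound)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a force trace written by [write_trace()]
#'
#' @param path input file.
#' @return an [ot_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (!length(hdr_idx) || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1) {
    stop("malformed trace file: header '#key=value' lines must come first")
  }
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^#([^=]+)=(.*)$", hdr))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad)) {
    stop("malformed header at line ", hdr_idx[bad[1]], ": ",
         hdr[bad[1]])
  }
  meta <- stats::setNames(vapply(kv, `[`, character(1), 3),
                          vapply(kv, `[`, character(1), 2))
  for (req in c("sampling_hz", "downsample_factor", "mode")) {
    if (!req %in% names(meta)) {
      stop("trace header is missing required key '", req, "'")
    }
  }
  body <- utils::read.table(text = lines[-hdr_idx], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  known <- c("time_s", "force_pN", "extension_nm", "truth_state",
             "truth_bound")
  extra <- setdiff(names(body), known)
  if (length(extra)) {
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  }
  if (!all(c("time_s", "force_pN") %in% names(body))) {
    stop("trace table must contain time_s and force_pN columns")
  }
  dt <- diff(body$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-5 * stats::median(dt)) {
    bad_row <- which(dt <= 0 | abs(dt - stats::median(dt)) >
                       1e-5 * stats::median(dt))[1]
    stop("non-uniform time grid near data line ", bad_row + 1)
  }
  tr <- ot_trace(
    time = body$time_s, force = body$force_pN,
    extension = body$extension_nm,
    sampling_hz = as.numeric(meta["sampling_hz"]),
    downsample_factor = as.integer(meta["downsample_factor"]),
    mode = meta[["mode"]],
    trap_separation = as.numeric(meta["trap_separation_nm"]),
    truth_state = body$truth_state,
    truth_bound = if (!is.null(body$truth_bound)) {
      as.logical(body$truth_bound)
    } else NULL)
  tr$extra_columns <- if (length(extra)) body[extra] else NULL
  tr
}

#' Read a secondary structure file
#'
#' Three-line dialect: line 1 \code{">name offset=<first residue>"},
#' line 2 the sequence, line 3 the dot-bracket string.
#'
#' @param path input file.
#' @return a [secondary_structure()].
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3 || !startsWith(lines[1], ">")) {
    stop("structure file must be a 3-line record: >name offset=N, ",
         "sequence, dot-bracket")
  }
  m <- regexec("^>\\s*(\\S+)(?:\\s+offset=(\\d+))?\\s*$", lines[1])
  parts <- regmatches(lines[1], m)[[1]]
  if (!length(parts)) stop("malformed structure header: ", lines[1])
  offset <- if (nzchar(parts[3])) as.integer(parts[3]) else 1L
  secondary_structure(trimws(lines[2]), trimws(lines[3]),
                      name = parts[2], numbering_offset = offset)
}

#' @rdname read_structure
#' @param struct a [secondary_structure()].
#' @export
write_structure <- function(struct, path) {
  writeLines(c(sprintf(">%s offset=%d", struct$name,
                       struct$numbering_offset),
               struct$sequence, struct$dot_bracket), path)
  invisible(path)
}

#' Serialize an elastic model to a flat key-value config section
#'
#' Keys carry their units (e.g. \code{ss_contour_per_nt_nm}); unknown keys
#' on read are rejected.
#'
#' @param model an [elastic_model()].
#' @return named character vector of "key = value" lines.
#' @export
elastic_model_to_config <- function(model) {
  c(kT_pNnm = model$kT,
    trap_stiffness_pN_per_nm = model$trap_stiffness,
    handle_contour_nm = model$handle_contour,
    handle_persistence_nm = model$handle_persistence,
    handle_stretch_modulus_pN = model$handle_stretch_modulus,
    ss_contour_per_nt_nm = model$ss_contour_per_nt,
    ss_persistence_nm = model$ss_persistence,
    folded_offset_nm = model$folded_offset)
}

#' @rdname elastic_model_to_config
#' @param values named numeric vector or list as produced by
#'   [elastic_model_to_config()].
#' @export
elastic_model_from_config <- function(values) {
  values <- unlist(values)
  known <- names(elastic_model_to_config(elastic_model()))
  unknown <- setdiff(names(values), known)
  if (length(unknown)) {
    stop("unknown elastic-model keys: ", paste(unknown, collapse = ", "))
  }
  defaults <- elastic_model_to_config(elastic_model())
  v <- defaults
  v[names(values)] <- as.numeric(values)
  elastic_model(kT = v[["kT_pNnm"]],
                trap_stiffness = v[["trap_stiffness_pN_per_nm"]],
                handle_contour = v[["handle_contour_nm"]],
                handle_persistence = v[["handle_persistence_nm"]],
                handle_stretch_modulus = v[["handle_stretch_modulus_pN"]],
                ss_contour_per_nt = v[["ss_contour_per_nt_nm"]],
                ss_persistence = v[["ss_persistence_nm"]],
                folded_offset = v[["folded_offset_nm"]])
}

#' Read / write a sectioned key-value run configuration
#'
#' INI-style plain text: \code{[section]} headers followed by
#' \code{key = value} lines; '#' starts a comment. Values are returned as
#' character and converted by the consumers; unknown sections are allowed
#' (each consumer validates its own keys).
#'
#' @param path file path.
#' @return named list of sections, each a named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      out[[section]] <- c(out[[section]], stats::setNames(val, key))
    } else {
      stop("malformed config line: ", ln)
    }
  }
  out
}

#' @rdname read_config
#' @param config named list of sections (named character/numeric vectors).
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (s in names(config)) {
    lines <- c(lines, sprintf("[%s]", s),
               sprintf("%s = %s", names(config[[s]]),
                       vapply(config[[s]], format, character(1))),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a dwell table as TSV
#'
#' Columns: \code{state}, \code{t_start} (s), \code{duration} (s),
#' \code{mean_force} (pN) and, when present, \code{phase}.
#'
#' @param dwells a \code{dwell_table}.
#' @param path file path.
#' @return \code{path} (writer) or the dwell table (reader).
#' @export
write_dwells <- function(dwells, path) {
  utils::write.table(as.data.frame(dwells), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' Write an analysis result as a JSON block
#'
#' Serializes a named list of results (estimates, confidence intervals,
#' problem sizes) to pretty-printed JSON with scalars unboxed.
#'
#' @param x named list (nested lists and data.frames allowed).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
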