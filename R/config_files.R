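# Flat key/value configuration files: one `key = value` (or `key: value`)
# pair per line, keys mirroring the constructor argument names exactly;
# unknown keys are errors (typo safety).  JSON files (detected by a ".json"
# extension or a leading "{") are accepted too.

parse_flat_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (grepl("\\.json$", path) || grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  out <- list()
  for (line in txt) {
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]?\\s+?(.*)$",
                                  line))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line: '", line, "'", call. = FALSE)
    key <- m[2]
    val <- trimws(gsub("[:=]", " ", m[3]))
    parts <- strsplit(val, "[,\\s]+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Read a device configuration or parameter vector from a flat file
#'
#' Keys must mirror the [device_config()] / [deposition_params()] argument
#' names exactly; unknown keys raise an error.
#'
#' @param path a flat `key = value` text file or a JSON file.
#' @return A `"device_config"` / `"deposition_params"`.
#' @export
read_device_config <- function(path) {
  kv <- parse_flat_config(path)
  known <- names(formals(device_config))
  bad <- setdiff(names(kv), known)
  if (length(bad))
    stop("unknown device_config keys in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(device_config, kv)
}

#' @rdname read_device_config
#' @export
read_deposition_params <- function(path) {
  kv <- parse_flat_config(path)
  bad <- setdiff(names(kv), param_names())
  if (length(bad))
    stop("unknown parameter keys in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(param_names(), names(kv))
  if (length(missing))
    stop("missing parameters in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(deposition_params, kv[param_names()])
}
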