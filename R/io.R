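# TSV output with a commented metadata header, and the flat key-value
# configuration grammar of the command-line interface.

#' Write a table as TSV with a commented metadata header
#'
#' Numeric columns are written at 17 significant digits so the file
#' round-trips bit-exactly through [read_table_meta()].
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param metadata Named list recorded as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_table_meta <- function(rows, path, metadata = list()) {
  stopifnot(is.data.frame(rows))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  meta <- c(
    list(package = paste0("pspeckle ",
                          as.character(utils::packageVersion("pspeckle")))),
    metadata
  )
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(format(meta[[k]], digits = 17), collapse = " ")),
               con)
  }
  fmt <- vapply(rows, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(rows)) |> rlang::set_names(NULL))
  fmt <- matrix(as.character(fmt), nrow = nrow(rows))
  writeLines(paste(names(rows), collapse = "\t"), con)
  writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a TSV written by [write_table_meta()]
#'
#' @param path File path.
#' @return A tibble; the parsed header is attached as attribute
#'   `metadata` (a named character list).
#' @export
read_table_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "# ")
  header <- lines[is_meta & seq_along(lines) <= which.min(is_meta)]
  n_meta <- length(header)
  meta <- list()
  for (l in header) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\x01\\2", l)
    kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  out <- utils::read.delim(text = lines[-seq_len(n_meta)], sep = "\t",
                           check.names = FALSE)
  out <- tibble::as_tibble(out)
  attr(out, "metadata") <- meta
  out
}

# ---- configuration ---------------------------------------------------------

.config_keys <- c(
  "preset", "command", "NA", "NB", "NC", "chiB", "chiAB", "vA", "vC", "Cs",
  "logzeta", "phip", "n", "alpha", "grid", "bracket", "out", "tend", "nmax",
  "seed"
)

# "lo:hi:step" -> numeric grid
.parse_grid <- function(s) {
  parts <- suppressWarnings(as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3 || any(is.na(parts)) || parts[3] == 0) {
    stop("malformed grid '", s, "': expected lo:hi:step")
  }
  seq(parts[1], parts[2], by = parts[3])
}

#' Load a run configuration from a flat key-value file and/or overrides
#'
#' The configuration grammar is flat `key = value` lines (`#` comments
#' allowed); ranges use `lo:hi:step`. Command-line flags override file
#' values. A preset must be named before any physical parameter defaults
#' exist; overrides win over preset values.
#'
#' @param path Optional path to a key-value config file.
#' @param overrides Named list of flag overrides.
#' @return A list of class `run_config` with validated entries `params`
#'   (a [micelle_params()] or `NULL`), `kinetics`, and the raw fields.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (l in lines) {
      m <- regmatches(l, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.+)$", l))[[1]]
      if (length(m) != 3) stop("malformed config line: '", l, "'")
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  kv <- utils::modifyList(kv, overrides)
  unknown <- setdiff(names(kv), .config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  num <- function(key) if (is.null(kv[[key]])) NULL else {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("value of '", key, "' is not a number: ", kv[[key]])
    v
  }
  params <- NULL
  phys <- c("NA", "NB", "NC", "chiB", "chiAB", "vA", "vC", "Cs")
  if (!is.null(kv$preset)) {
    ov <- list(N_A = num("NA"), N_B = num("NB"), N_C = num("NC"),
               chi_B = num("chiB"), chi_AB = num("chiAB"),
               v_A = num("vA"), v_C = num("vC"), C_s = num("Cs"))
    ov <- ov[!vapply(ov, is.null, TRUE)]
    params <- do.call(preset_params, c(list(preset = kv$preset), ov))
  } else if (any(phys %in% names(kv))) {
    stop("physical parameters require an explicit preset ",
         "(no defaults without one)")
  }
  kinetics <- NULL
  if (!is.null(kv$logzeta) && !grepl(":", kv$logzeta)) {
    kinetics <- kinetic_params(log_zeta = num("logzeta"),
                               phi_p = num("phip") %||% 0)
  } else if (!is.null(kv$preset)) {
    kinetics <- preset_kinetics(kv$preset)
  }
  structure(
    list(params = params, kinetics = kinetics, fields = kv),
    class = "run_config"
  )
}
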