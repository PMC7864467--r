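# Reading and writing the tabular files, the YAML problem file, and
# COMBINE archives.  TSV dialect: TAB-delimited, UTF-8, header row, no
# quoting (cells must not contain TAB); empty cell = missing value.

#' Read one PEtab table
#'
#' @param path Path to a tab-separated file with a header row.
#' @param role One of `"condition"`, `"measurement"`, `"observable"`,
#'   `"parameter"`, `"visualization"`.
#' @return A canonical data.frame; columns not in the v1 vocabulary are kept
#'   and listed in `attr(, "extension_columns")`.
#' @export
read_petab_table <- function(path, role) {
  if (!file.exists(path)) {
    petab_error("missing_file", sprintf("file not found: %s", path),
                path = path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), comment.char = "",
                          stringsAsFactors = FALSE)
  .canonicalize_table(df, role, source = basename(path))
}

#' Write one PEtab table
#'
#' Column order on disk: required columns in documented order, then optional
#' columns present, then extension columns in their original order.
#' `read_petab_table(write_petab_table(x))` is the identity up to that
#' canonical column order.
#'
#' @param df Canonical table data.frame.
#' @param role Table role, see [read_petab_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_petab_table <- function(df, role, path) {
  reg <- .petab_columns[[role]]
  if (is.null(reg)) petab_error("bad_role", sprintf("unknown role '%s'", role))
  known <- c(reg$required, reg$optional)
  cols <- c(intersect(reg$required, names(df)),
            intersect(reg$optional, names(df)),
            setdiff(names(df), known))
  cells <- lapply(cols, function(col) {
    v <- df[[col]]
    if (is.numeric(v)) format_petab_number(v)
    else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      v
    }
  })
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(df) > 0L) do.call(paste, c(cells, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- YAML problem file -----------------------------------------------------
# Schema (format v1):
#   format_version: 1
#   parameter_file: <path>
#   problems:
#     - sbml_files: [<path>]
#       condition_files: [...]
#       measurement_files: [...]
#       observable_files: [...]
#       visualization_files: [...]   # optional
# Multiple `problems` entries and multiple files per list are concatenated
# in listed order.

#' Load a PEtab problem from its YAML file
#'
#' All referenced files are read; multiple measurement/condition/observable
#' files are concatenated in the listed order.  The returned problem is
#' deliberately un-validated: run [lint_problem()] or [assert_petab_valid()]
#' explicitly.
#'
#' @param yaml_path Path to the problem YAML file.
#' @return A `petab_problem`.
#' @export
load_petab_problem <- function(yaml_path) {
  if (!file.exists(yaml_path)) {
    petab_error("missing_file", sprintf("file not found: %s", yaml_path),
                path = yaml_path)
  }
  spec <- tryCatch(yaml::read_yaml(yaml_path),
                   error = function(e) {
                     petab_error("yaml_schema",
                                 sprintf("cannot parse YAML %s: %s",
                                         yaml_path, conditionMessage(e)))
                   })
  if (is.null(spec$format_version)) {
    petab_error("yaml_schema", "YAML lacks required key 'format_version'")
  }
  if (as.integer(spec$format_version) != 1L) {
    petab_error("unsupported_version",
                sprintf("unsupported format_version %s",
                        spec$format_version))
  }
  if (is.null(spec$parameter_file) || is.null(spec$problems)) {
    petab_error("yaml_schema",
                "YAML must define 'parameter_file' and 'problems'")
  }
  base <- dirname(normalizePath(yaml_path))
  resolve <- function(p) {
    full <- file.path(base, p)
    if (!file.exists(full)) {
      petab_error("missing_file", sprintf("referenced file not found: %s", p),
                  path = full)
    }
    full
  }
  read_many <- function(paths, role) {
    if (length(paths) == 0L) return(NULL)
    parts <- lapply(paths, function(p) read_petab_table(resolve(p), role))
    ext <- unique(unlist(lapply(parts, attr, "extension_columns")))
    all_cols <- unique(unlist(lapply(parts, names)))
    parts <- lapply(parts, function(d) {
      for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
      d[all_cols]
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "extension_columns") <- ext
    out
  }
  sbml_files <- unlist(lapply(spec$problems, `[[`, "sbml_files"))
  if (length(sbml_files) > 1L) {
    petab_error("yaml_schema",
                "exactly one SBML model per problem is supported")
  }
  model <- if (length(sbml_files) == 1L) {
    load_sbml_model(resolve(sbml_files[[1]]))
  } else NULL
  conditions <- read_many(unlist(lapply(spec$problems, `[[`,
                                        "condition_files")), "condition")
  measurements <- read_many(unlist(lapply(spec$problems, `[[`,
                                          "measurement_files")),
                            "measurement")
  observables <- read_many(unlist(lapply(spec$problems, `[[`,
                                         "observable_files")), "observable")
  visualization <- read_many(unlist(lapply(spec$problems, `[[`,
                                           "visualization_files")),
                             "visualization")
  parameters <- read_petab_table(resolve(spec$parameter_file), "parameter")
  petab_problem(model = model, conditions = conditions,
                measurements = measurements, observables = observables,
                parameters = parameters, visualization = visualization,
                yaml_path = normalizePath(yaml_path))
}

#' Write a PEtab problem to a directory
#'
#' Emits the SBML model, the five tables and the grouping YAML file.  An
#' empty visualization table is omitted entirely (no file, no YAML key).
#'
#' @param problem A `petab_problem`.
#' @param directory Output directory (created if absent).
#' @param name Base name used for the emitted files.
#' @return Path of the written YAML file, invisibly.
#' @export
save_petab_problem <- function(problem, directory, name = "problem") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    model = paste0(name, "_model.xml"),
    conditions = paste0(name, "_conditions.tsv"),
    measurements = paste0(name, "_measurements.tsv"),
    observables = paste0(name, "_observables.tsv"),
    parameters = paste0(name, "_parameters.tsv")
  )
  if (is.null(problem$model) || is.null(problem$model$xml_text)) {
    petab_error("no_model", "problem has no model to write")
  }
  writeLines(problem$model$xml_text,
             file.path(directory, files$model), useBytes = TRUE)
  write_petab_table(problem$conditions, "condition",
                    file.path(directory, files$conditions))
  write_petab_table(problem$measurements, "measurement",
                    file.path(directory, files$measurements))
  write_petab_table(problem$observables, "observable",
                    file.path(directory, files$observables))
  write_petab_table(problem$parameters, "parameter",
                    file.path(directory, files$parameters))
  entry <- list(sbml_files = list(files$model),
                condition_files = list(files$conditions),
                measurement_files = list(files$measurements),
                observable_files = list(files$observables))
  if (!is.null(problem$visualization) && nrow(problem$visualization) > 0L) {
    vis_file <- paste0(name, "_visualization.tsv")
    write_petab_table(problem$visualization, "visualization",
                      file.path(directory, vis_file))
    entry$visualization_files <- list(vis_file)
  }
  yaml_file <- file.path(directory, paste0(name, ".yaml"))
  yaml::write_yaml(list(format_version = 1L,
                        parameter_file = files$parameters,
                        problems = list(entry)),
                   yaml_file)
  invisible(yaml_file)
}

# ---- COMBINE archive (OMEX) ------------------------------------------------

.omex_format_uri <- function(file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    xml = "http://identifiers.org/combine.specifications/sbml.level-2.version-4",
    tsv = "http://purl.org/NET/mediatypes/text/tab-separated-values",
    yaml = ,
    yml = "http://purl.org/NET/mediatypes/application/x-yaml",
    "http://purl.org/NET/mediatypes/application/octet-stream")
}

#' Package a PEtab problem as a COMBINE archive
#'
#' Writes an OMEX zip containing the SBML model, the tables, the YAML
#' problem file and a `manifest.xml` declaring each entry's format; the YAML
#' file is flagged as the archive's master file.
#'
#' @param problem A `petab_problem`.
#' @param path Output `.omex`/`.zip` path.
#' @param name Base name for the archived files.
#' @return `path`, invisibly.
#' @export
create_combine_archive <- function(problem, path, name = "problem") {
  stage <- tempfile("omex_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  yaml_file <- save_petab_problem(problem, stage, name = name)
  entries <- list.files(stage)
  manifest <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<omexManifest xmlns="http://identifiers.org/combine.specifications/omex-manifest">',
    '  <content location="." format="http://identifiers.org/combine.specifications/omex"/>',
    '  <content location="./manifest.xml" format="http://identifiers.org/combine.specifications/omex-manifest"/>',
    vapply(entries, function(f) {
      master <- identical(f, basename(yaml_file))
      sprintf('  <content location="./%s" format="%s"%s/>', f,
              .omex_format_uri(f), if (master) ' master="true"' else "")
    }, character(1)),
    '</omexManifest>')
  writeLines(manifest, file.path(stage, "manifest.xml"), useBytes = TRUE)
  files <- list.files(stage, full.names = TRUE)
  names(files) <- basename(files)
  write_zip_archive(files, path)
  invisible(path)
}

#' Extract a COMBINE archive and load the problem it contains
#'
#' @param path Archive path.
#' @param exdir Extraction directory.
#' @return A `petab_problem`.
#' @export
load_combine_archive <- function(path, exdir = tempfile("omex_x_")) {
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  utils::unzip(path, exdir = exdir)
  manifest <- file.path(exdir, "manifest.xml")
  if (!file.exists(manifest)) {
    petab_error("bad_archive", "archive has no manifest.xml")
  }
  doc <- xml2::read_xml(manifest)
  xml2::xml_ns_strip(doc)
  contents <- xml2::xml_find_all(doc, ".//content")
  master <- contents[xml2::xml_attr(contents, "master") %in% "true"]
  if (length(master) == 0L) {
    petab_error("bad_archive", "archive manifest declares no master file")
  }
  loc <- sub("^\\./", "", xml2::xml_attr(master[[1]], "location"))
  load_petab_problem(file.path(exdir, loc))
}

# ---- minimal zip writer ----------------------------------------------------
# Store-only (no compression) zip, sufficient for OMEX archives of small
# text files.  Reading goes through utils::unzip.

.crc32_env <- new.env(parent = emptyenv())

.crc32_table <- function() {
  if (!is.null(.crc32_env$table)) return(.crc32_env$table)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  .crc32_env$table <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.le_bytes <- function(value, width) {
  out <- raw(width)
  v <- value
  for (i in seq_len(width)) {
    out[i] <- as.raw(bitwAnd(v, 255L))
    v <- bitwShiftR(v, 8L)
  }
  out
}

#' Write a stored (uncompressed) zip archive
#'
#' @param files Named character vector: values are paths on disk, names are
#'   the entry names inside the archive.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_zip_archive <- function(files, path) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("files must be a named vector of paths")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0L
  for (entry in names(files)) {
    data <- readBin(files[[entry]], "raw", n = file.size(files[[entry]]))
    crc <- .crc32(data)
    name_raw <- charToRaw(entry)
    header <- c(.le_bytes(0x04034b50L, 4L),  # local file header signature
                .le_bytes(20L, 2L),          # version needed
                .le_bytes(0L, 2L),           # flags
                .le_bytes(0L, 2L),           # method: stored
                .le_bytes(0L, 2L), .le_bytes(0L, 2L),  # mod time/date
                .le_bytes(crc, 4L),
                .le_bytes(length(data), 4L), .le_bytes(length(data), 4L),
                .le_bytes(length(name_raw), 2L), .le_bytes(0L, 2L))
    writeBin(header, con)
    writeBin(name_raw, con)
    if (length(data) > 0L) writeBin(data, con)
    central[[entry]] <- list(crc = crc, size = length(data),
                             name = name_raw, offset = offset)
    offset <- offset + length(header) + length(name_raw) + length(data)
  }
  cd_start <- offset
  cd_size <- 0L
  for (entry in names(files)) {
    e <- central[[entry]]
    rec <- c(.le_bytes(0x02014b50L, 4L),     # central directory signature
             .le_bytes(20L, 2L), .le_bytes(20L, 2L),
             .le_bytes(0L, 2L), .le_bytes(0L, 2L),
             .le_bytes(0L, 2L), .le_bytes(0L, 2L),
             .le_bytes(e$crc, 4L),
             .le_bytes(e$size, 4L), .le_bytes(e$size, 4L),
             .le_bytes(length(e$name), 2L),
             .le_bytes(0L, 2L), .le_bytes(0L, 2L),
             .le_bytes(0L, 2L), .le_bytes(0L, 2L),
             .le_bytes(0L, 4L),
             .le_bytes(e$offset, 4L))
    writeBin(rec, con)
    writeBin(e$name, con)
    cd_size <- cd_size + length(rec) + length(e$name)
  }
  eocd <- c(.le_bytes(0x06054b50L, 4L),
            .le_bytes(0L, 2L), .le_bytes(0L, 2L),
            .le_bytes(length(files), 2L), .le_bytes(length(files), 2L),
            .le_bytes(cd_size, 4L), .le_bytes(cd_start, 4L),
            .le_bytes(0L, 2L))
  writeBin(eocd, con)
  invisible(path)
}
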