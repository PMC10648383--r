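# TPS and CSV landmark input/output with validation.
#
# The wide CSV dialect carries full metadata:
#   id, species, sex, observer, site, replicate, x1, y1, ..., xk, yk
# The TPS dialect (tpsDIG conventions: LM=, coordinate lines, ID=, IMAGE=,
# SCALE=) carries coordinates and specimen id only; species/sex/observer
# metadata read from TPS default to "unknown"/"obs1".

#' Read a TPS landmark file
#'
#' Accepts the tpsDIG record layout: an `LM=<k>` line, k whitespace-separated
#' `x y` coordinate lines, then optional `ID=`, `IMAGE=`, `SCALE=` lines.
#' Unknown keys (e.g. `CURVES=`) are skipped with a warning. If `SCALE=s` is
#' present, all coordinates of that record are multiplied by `s`. The specimen
#' id is taken from `ID=`, falling back to the `IMAGE=` basename, then to a
#' running index. Records are returned in file order; a record is never
#' silently dropped.
#'
#' @param path Path to a TPS file.
#' @return A landmark tibble (one row per record).
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("TPS file not found: ", path), class = "wingmorph_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lm_idx <- grep("^\\s*LM\\s*=", lines, ignore.case = TRUE)
  if (length(lm_idx) == 0L) {
    abort("No LM= records found in TPS file.", class = "wingmorph_parse_error")
  }
  ends <- c(lm_idx[-1L] - 1L, length(lines))
  unknown_keys <- character()

  recs <- vector("list", length(lm_idx))
  for (r in seq_along(lm_idx)) {
    start <- lm_idx[r]
    block <- lines[start:ends[r]]
    k_str <- sub("^\\s*LM\\s*=\\s*", "", block[1L], ignore.case = TRUE)
    k <- suppressWarnings(as.integer(k_str))
    if (is.na(k) || k < 1L) {
      abort(sprintf("Record %d (line %d): invalid LM= count '%s'.", r, start, k_str),
            class = "wingmorph_parse_error")
    }
    body <- block[-1L]
    body <- body[trimws(body) != ""]
    is_key <- grepl("^\\s*[A-Za-z_]+\\s*=", body)
    coord_lines <- body[!is_key]
    key_lines <- body[is_key]
    if (length(coord_lines) != k) {
      abort(sprintf("Record %d (line %d): expected %d coordinate lines, found %d.",
                    r, start, k, length(coord_lines)),
            class = "wingmorph_malformed_record")
    }
    toks <- strsplit(trimws(coord_lines), "\\s+")
    if (any(lengths(toks) != 2L)) {
      bad <- which(lengths(toks) != 2L)[1L]
      abort(sprintf("Record %d: coordinate line %d does not have two tokens.", r, bad),
            class = "wingmorph_parse_error")
    }
    vals <- suppressWarnings(as.numeric(unlist(toks)))
    if (anyNA(vals)) {
      bad <- which(is.na(matrix(vals, ncol = 2L, byrow = TRUE)), arr.ind = TRUE)[1L, 1L]
      abort(sprintf("Record %d: non-numeric coordinate token on coordinate line %d.", r, bad),
            class = "wingmorph_parse_error")
    }
    keys <- toupper(sub("\\s*=.*$", "", trimws(key_lines)))
    key_vals <- sub("^[^=]*=\\s*", "", trimws(key_lines))
    known <- keys %in% c("ID", "IMAGE", "SCALE")
    unknown_keys <- union(unknown_keys, keys[!known])
    scale <- if ("SCALE" %in% keys) {
      s <- suppressWarnings(as.numeric(key_vals[match("SCALE", keys)]))
      if (is.na(s)) {
        abort(sprintf("Record %d: non-numeric SCALE value.", r), class = "wingmorph_parse_error")
      }
      s
    } else 1
    id <- if ("ID" %in% keys) {
      key_vals[match("ID", keys)]
    } else if ("IMAGE" %in% keys) {
      sub("\\.[A-Za-z0-9]+$", "", basename(key_vals[match("IMAGE", keys)]))
    } else {
      sprintf("record%03d", r)
    }
    recs[[r]] <- list(k = k, id = id, coords = vals * scale)
  }

  ks <- vapply(recs, function(x) x$k, integer(1))
  if (length(unique(ks)) > 1L) {
    abort(sprintf("Heterogeneous dataset: LM= values %s differ across records.",
                  paste(unique(ks), collapse = ", ")),
          class = "wingmorph_heterogeneous_error")
  }
  if (length(unknown_keys)) {
    warn(paste0("Ignoring unknown TPS key(s): ", paste(unknown_keys, collapse = ", ")))
  }
  mat <- do.call(rbind, lapply(recs, function(x) x$coords))
  new_landmark_tbl(default_meta(length(recs), vapply(recs, function(x) x$id, character(1))), mat)
}

#' Write a TPS landmark file
#'
#' Emits one `LM=` record per row in row order, coordinates formatted with
#' nine decimal places (byte-stable output), and `ID=` from `specimen_id`.
#' TPS carries no species/sex/observer metadata; use [write_landmark_csv()]
#' to preserve it.
#'
#' @param data Landmark tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  check_writable_dataset(data)
  k <- landmark_count(data)
  mat <- coord_matrix(data)
  out <- character(0)
  for (i in seq_len(nrow(data))) {
    cfg <- as_config(mat[i, ])
    out <- c(out,
             sprintf("LM=%d", k),
             sprintf("%.9f %.9f", cfg[, 1L], cfg[, 2L]),
             sprintf("ID=%s", data$specimen_id[i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a wide landmark CSV
#'
#' Expects header columns `id, species, sex, observer, site, replicate`,
#' then `x1, y1, ..., xk, yk` (k inferred from the header). Species and sex
#' strings are normalized to the declared enums; unrecognized values map to
#' `"unknown"` with a warning.
#'
#' @param path Path to a CSV file.
#' @return A landmark tibble.
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("CSV file not found: ", path), class = "wingmorph_io_error")
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character"),
    error = function(e) abort(paste0("CSV parse failure: ", conditionMessage(e)),
                              class = "wingmorph_parse_error")
  )
  need <- c("id", "species", "sex", "observer", "site", "replicate")
  missing_meta <- setdiff(need, names(df))
  if (length(missing_meta)) {
    abort(paste0("CSV schema error: missing column(s) ",
                 paste(missing_meta, collapse = ", ")),
          class = "wingmorph_schema_error")
  }
  xs <- grep("^x[0-9]+$", names(df), value = TRUE)
  k <- length(xs)
  if (k == 0L || !all(coord_cols(k) %in% names(df))) {
    abort("CSV schema error: incomplete coordinate columns (need x1..xk, y1..yk).",
          class = "wingmorph_schema_error")
  }
  coords <- as.matrix(df[coord_cols(k)])
  suppressWarnings(storage.mode(coords) <- "double")
  if (anyNA(coords)) {
    bad <- which(rowSums(is.na(coords)) > 0L)[1L]
    abort(sprintf("CSV parse error: non-numeric or missing coordinate in data row %d.", bad),
          class = "wingmorph_parse_error")
  }
  repl <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(repl)) {
    abort("CSV parse error: non-integer replicate value.", class = "wingmorph_parse_error")
  }
  meta <- tibble::tibble(
    specimen_id = df$id,
    species = normalize_species(df$species),
    sex = normalize_sex(df$sex),
    observer = df$observer,
    site = ifelse(df$site == "" | is.na(df$site), NA_character_, df$site),
    replicate = repl
  )
  new_landmark_tbl(meta, coords)
}

#' Write a wide landmark CSV
#'
#' Deterministic byte output: fixed column order, rows in input order,
#' coordinates with nine decimal places, "." decimal separator, UTF-8.
#'
#' @param data Landmark tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(data, path) {
  check_writable_dataset(data)
  k <- landmark_count(data)
  mat <- coord_matrix(data)
  header <- paste(c("id", "species", "sex", "observer", "site", "replicate",
                    coord_cols(k)), collapse = ",")
  coord_txt <- apply(mat, 1L, function(v) paste(sprintf("%.9f", v), collapse = ","))
  rows <- paste(data$specimen_id, data$species, data$sex, data$observer,
                ifelse(is.na(data$site), "", data$site), data$replicate,
                coord_txt, sep = ",")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

check_writable_dataset <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("Refusing to write an empty dataset.", class = "wingmorph_validation_error")
  }
  landmark_count(data)
  if (!all(META_COLS %in% names(data))) {
    abort(paste0("Dataset missing metadata column(s): ",
                 paste(setdiff(META_COLS, names(data)), collapse = ", ")),
          class = "wingmorph_schema_error")
  }
  invisible(TRUE)
}

#' Validate a landmark dataset
#'
#' Pure reporting: returns a tibble of issues, one row per problem found, and
#' never mutates the input. Checks per record: non-finite coordinates,
#' exactly coincident landmarks, missing metadata; and dataset-wide:
#' duplicate (specimen_id, observer, replicate) keys, species/sex values
#' outside the declared enums, and mixed chirality (the sign of the signed
#' area of each record's convex hull must agree across records — all wings
#' must be digitized with the same handedness because alignment excludes
#' reflections).
#'
#' @param data Landmark tibble.
#' @return Tibble with columns `record` (row index, NA for dataset-level
#'   issues), `issue` (short code), `detail`.
#' @export
validate_landmarks <- function(data) {
  issues <- list()
  add <- function(record, issue, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      record = as.integer(record), issue = issue, detail = detail)
  }
  if (nrow(data) == 0L) {
    add(NA, "empty_dataset", "dataset has no records")
    return(dplyr::bind_rows(issues))
  }
  k <- landmark_count(data)
  mat <- coord_matrix(data)

  for (i in seq_len(nrow(data))) {
    cfg <- as_config(mat[i, ])
    if (any(!is.finite(cfg))) {
      add(i, "nonfinite_coordinate", "record contains non-finite coordinates")
      next
    }
    dd <- as.matrix(stats::dist(cfg))
    diag(dd) <- Inf
    if (any(dd == 0)) {
      pair <- which(dd == 0, arr.ind = TRUE)[1L, ]
      add(i, "coincident_landmarks",
          sprintf("landmarks %d and %d coincide exactly", min(pair), max(pair)))
    }
  }

  key <- paste(data$specimen_id, data$observer, data$replicate, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  for (i in which(dup & !duplicated(key))) {
    add(i, "duplicate_key",
        sprintf("(id=%s, observer=%s, replicate=%d) appears more than once",
                data$specimen_id[i], data$observer[i], data$replicate[i]))
  }
  bad_sp <- which(!data$species %in% SPECIES_LEVELS)
  for (i in bad_sp) add(i, "invalid_species", data$species[i])
  bad_sx <- which(!data$sex %in% SEX_LEVELS)
  for (i in bad_sx) add(i, "invalid_sex", data$sex[i])
  miss_id <- which(is.na(data$specimen_id) | data$specimen_id == "")
  for (i in miss_id) add(i, "missing_metadata", "empty specimen_id")
  if (any(is.na(data$replicate) | data$replicate < 1L)) {
    for (i in which(is.na(data$replicate) | data$replicate < 1L)) {
      add(i, "invalid_replicate", "replicate must be an integer >= 1")
    }
  }

  # chirality: the signed (shoelace) area of the polygon traced in landmark
  # order flips sign under reflection but not under rotation/translation;
  # a convex hull cannot be used because hull algorithms re-orient vertices
  signs <- vapply(seq_len(nrow(data)), function(i) {
    cfg <- as_config(mat[i, ])
    if (any(!is.finite(cfg))) return(NA_real_)
    x <- cfg[, 1L]; y <- cfg[, 2L]
    sign(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y))
  }, numeric(1))
  ok <- !is.na(signs) & signs != 0
  if (length(unique(signs[ok])) > 1L) {
    minority <- names(which.min(table(signs[ok])))
    for (i in which(ok & signs == as.numeric(minority))) {
      add(i, "chirality_mismatch",
          "hull orientation differs from the rest of the dataset (reflected wing?)")
    }
  }

  if (length(issues) == 0L) {
    return(tibble::tibble(record = integer(), issue = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}
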