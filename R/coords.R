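# Shared helpers for the wide landmark table: one row per digitized
# configuration, metadata columns plus interleaved coordinate columns
# x1, y1, ..., xk, yk.

SPECIES_LEVELS <- c("japonicus", "koreicus", "unknown")
SEX_LEVELS <- c("female", "male", "unknown")
META_COLS <- c("specimen_id", "species", "sex", "observer", "site", "replicate")

#' Coordinate column names for k landmarks
#'
#' @param k Number of landmarks.
#' @return Character vector `x1, y1, ..., xk, yk`.
#' @export
coord_cols <- function(k) {
  as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
}

#' Number of landmarks in a landmark table
#'
#' Infers k from the `x*`/`y*` column pairs and checks the pairing is
#' complete.
#'
#' @param data Landmark tibble.
#' @return Integer landmark count.
#' @export
landmark_count <- function(data) {
  xs <- grep("^x[0-9]+$", names(data), value = TRUE)
  ys <- grep("^y[0-9]+$", names(data), value = TRUE)
  k <- length(xs)
  if (k == 0L) {
    abort("No coordinate columns (x1, y1, ...) found.", class = "wingmorph_schema_error")
  }
  if (!setequal(xs, paste0("x", seq_len(k))) || !setequal(ys, paste0("y", seq_len(k))) ||
      length(ys) != k) {
    abort("Coordinate columns must be the complete set x1..xk, y1..yk.",
          class = "wingmorph_schema_error")
  }
  k
}

#' Extract the n x 2k coordinate matrix from a landmark table
#'
#' Rows are specimens, columns interleaved `x1, y1, ..., xk, yk` (the flat
#' shape-vector layout used throughout).
#'
#' @param data Landmark tibble.
#' @return Numeric matrix, one flattened configuration per row.
#' @export
coord_matrix <- function(data) {
  k <- landmark_count(data)
  m <- as.matrix(data[coord_cols(k)])
  storage.mode(m) <- "double"
  m
}

# flat 2k vector -> k x 2 configuration matrix
as_config <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

# k x 2 configuration -> flat 2k vector (x1, y1, ...)
flatten_config <- function(m) as.vector(t(m))

# n x 2k matrix -> tibble of coordinate columns
coords_as_cols <- function(mat) {
  k <- ncol(mat) / 2L
  colnames(mat) <- coord_cols(k)
  tibble::as_tibble(mat)
}

# replace the coordinate columns of `data` with the rows of `mat`
set_coords <- function(data, mat) {
  k <- landmark_count(data)
  stopifnot(nrow(mat) == nrow(data), ncol(mat) == 2L * k)
  data[coord_cols(k)] <- coords_as_cols(mat)
  data
}

meta_cols_present <- function(data) intersect(META_COLS, names(data))

#' Normalize free-text species labels to the declared enum
#'
#' Matching is case- and whitespace-insensitive; any string containing
#' "koreicus" or "japonicus" maps to that level, anything else maps to
#' `"unknown"` with a warning.
#'
#' @param x Character vector of species labels.
#' @return Character vector with values in japonicus/koreicus/unknown.
#' @export
normalize_species <- function(x) {
  low <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep("unknown", length(x))
  out[grepl("koreicus", low)] <- "koreicus"
  out[grepl("japonicus", low)] <- "japonicus"
  bad <- !is.na(x) & out == "unknown" & !grepl("unknown", low) & nzchar(low)
  if (any(bad)) {
    warn(paste0("Unrecognized species label(s) mapped to 'unknown': ",
                paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Normalize free-text sex labels to the declared enum
#'
#' @param x Character vector of sex labels ("f"/"female"/"m"/"male", any case).
#' @return Character vector with values in female/male/unknown.
#' @export
normalize_sex <- function(x) {
  low <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep("unknown", length(x))
  out[low %in% c("f", "female", "fem")] <- "female"
  out[low %in% c("m", "male")] <- "male"
  bad <- !is.na(x) & out == "unknown" & !grepl("unknown", low) & nzchar(low)
  if (any(bad)) {
    warn(paste0("Unrecognized sex label(s) mapped to 'unknown': ",
                paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

# canonical empty landmark tibble with metadata defaults
new_landmark_tbl <- function(meta, mat) {
  k <- ncol(mat) / 2L
  dplyr::bind_cols(tibble::as_tibble(meta), coords_as_cols(mat))
}

default_meta <- function(n, specimen_id = NULL) {
  tibble::tibble(
    specimen_id = specimen_id %||% sprintf("spec%03d", seq_len(n)),
    species = "unknown",
    sex = "unknown",
    observer = "obs1",
    site = NA_character_,
    replicate = 1L
  )
}
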