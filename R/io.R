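#' Landmark configuration sets
#'
#' A `landmark_set` holds one cohort's raw landmark configurations: a
#' `k x 3 x n` coordinate array plus subject identifiers. All configurations
#' in a set share the same number and ordering of landmarks.
#'
#' @param coords list of `k x 3` numeric matrices, or a `k x 3 x n` array.
#' @param subject_id character vector of subject identifiers.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, subject_id) {
  if (is.array(coords) && length(dim(coords)) == 3L) {
    coords <- lapply(seq_len(dim(coords)[3]), function(i) coords[, , i])
  }
  stopifnot(is.list(coords), length(coords) == length(subject_id))
  if (length(coords) == 0L) {
    return(structure(list(coords = array(numeric(), dim = c(0, 3, 0)),
                          subject_id = character()),
                     class = "landmark_set"))
  }
  k <- nrow(coords[[1]])
  if (k < 3L) stop("landmark configurations need k >= 3 landmarks", call. = FALSE)
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != k) {
      stop("configuration for subject '", subject_id[i],
           "' is not a ", k, " x 3 matrix", call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop("non-finite coordinates for subject '", subject_id[i], "'",
           call. = FALSE)
    }
  }
  arr <- array(unlist(coords, use.names = FALSE), dim = c(k, 3L, length(coords)))
  # unlist() concatenates column-major per matrix, so refill explicitly
  for (i in seq_along(coords)) arr[, , i] <- coords[[i]]
  dimnames(arr) <- list(NULL, c("x", "y", "z"), subject_id)
  structure(list(coords = arr, subject_id = as.character(subject_id)),
            class = "landmark_set")
}

#' @export
length.landmark_set <- function(x) length(x$subject_id)

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", length(x), " configurations of ",
      if (length(x)) dim(x$coords)[1] else 0, " landmarks\n", sep = "")
  invisible(x)
}

n_landmarks <- function(x) dim(x$coords)[1]

#' Read a TPS landmark file (LM3 dialect)
#'
#' Parses 3D landmark records of the form `LM3=k`, followed by `k` lines of
#' three whitespace-separated coordinates, followed by `ID=<subject>`.
#' Landmark indices are 1-based both in files and in R.
#'
#' @param path path to a TPS file.
#' @return A [landmark_set()] with one configuration per record, in file order.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  coords <- list(); ids <- character(); rec <- 0L
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^LM=", ln, ignore.case = TRUE)) {
      stop("2D 'LM=' records are not supported (record ", rec + 1L,
           "); expected 3D 'LM3=' records", call. = FALSE)
    }
    if (!grepl("^LM3=", ln, ignore.case = TRUE)) {
      stop("malformed TPS file: expected 'LM3=' at line ", i, call. = FALSE)
    }
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM3=", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 1L) stop("invalid LM3 count in record ", rec, call. = FALSE)
    rows <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      if (i + j > length(lines) ||
          grepl("^(ID=|LM3=|LM=)", lines[i + j], ignore.case = TRUE)) {
        stop("record ", rec, ": LM3=", k, " but fewer coordinate lines found",
             call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(strsplit(lines[i + j], "\\s+")[[1]]))
      if (length(vals) != 3L || anyNA(vals)) {
        stop("record ", rec, ": coordinate line ", j,
             " does not contain 3 numbers", call. = FALSE)
      }
      rows[j, ] <- vals
    }
    i <- i + k + 1L
    if (i > length(lines) || !grepl("^ID=", lines[i], ignore.case = TRUE)) {
      if (i <= length(lines) && !grepl("^(LM3=|LM=)", lines[i], ignore.case = TRUE)) {
        stop("record ", rec, ": LM3=", k, " does not match the number of ",
             "coordinate lines", call. = FALSE)
      }
      stop("record ", rec, ": missing ID= line", call. = FALSE)
    }
    ids <- c(ids, sub("^ID=", "", lines[i], ignore.case = TRUE))
    coords <- c(coords, list(rows))
    i <- i + 1L
  }
  landmark_set(coords, ids)
}

#' Write a landmark set to a TPS file (LM3 dialect)
#'
#' Coordinates are written with 6 decimal places, so read/write round trips
#' are lossless to 1e-6.
#'
#' @param x a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- if (length(x)) n_landmarks(x) else 0L
  for (i in seq_len(length(x))) {
    writeLines(paste0("LM3=", k), con)
    m <- x$coords[, , i]
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
    writeLines(paste0("ID=", x$subject_id[i]), con)
  }
  invisible(path)
}

#' Read landmarks from a wide CSV
#'
#' Expects a header `subject_id, x1, y1, z1, ..., xk, yk, zk`.
#'
#' @param path path to the CSV file.
#' @return A [landmark_set()].
#' @export
read_landmarks_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("parse error in '", path, "' at row ", prob$row[1], ": ",
         prob$expected[1], call. = FALSE)
  }
  if (!"subject_id" %in% names(df)) {
    stop("landmark CSV is missing a 'subject_id' column", call. = FALSE)
  }
  coord_cols <- setdiff(names(df), "subject_id")
  if (length(coord_cols) %% 3L != 0L) {
    stop("coordinate columns are not a multiple of 3", call. = FALSE)
  }
  k <- length(coord_cols) / 3L
  expected <- shape_colnames(k)
  if (!identical(coord_cols, expected)) {
    stop("coordinate columns must be named ", expected[1], ", ", expected[2],
         ", ... in landmark order", call. = FALSE)
  }
  mat <- as.matrix(df[coord_cols])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[coord_cols], is.numeric, logical(1)))[1]
    stop("non-numeric coordinate column '", coord_cols[bad], "'", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("non-finite coordinate at row ",
         which(rowSums(!is.finite(mat)) > 0)[1], call. = FALSE)
  }
  coords <- lapply(seq_len(nrow(mat)), function(i) vector_to_config(mat[i, ], k))
  landmark_set(coords, df$subject_id)
}

#' Write landmarks to a wide CSV
#'
#' @param x a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(x, path) {
  shapes <- array_to_shapes(x$coords)
  df <- tibble::as_tibble(shapes)
  df <- dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Required columns: `subject_id`, `age`, `sex`, `syndrome`,
#' `diagnosis_status`. Optional: `family_id`, `camera`, `race`, `ethnicity`.
#' `"unaffected"` is a reserved syndrome label; relatives carry the syndrome
#' of their affected family member with `diagnosis_status = "relative"`.
#'
#' @param path path to the metadata CSV.
#' @return A tibble, one row per subject.
#' @export
read_metadata_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  required <- c("subject_id", "age", "sex", "syndrome", "diagnosis_status")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in metadata: ",
         df$subject_id[duplicated(df$subject_id)][1], call. = FALSE)
  }
  ok_sex <- is.na(df$sex) | df$sex %in% c("female", "male")
  if (!all(ok_sex)) {
    stop("sex must be 'female' or 'male' (subject ",
         df$subject_id[!ok_sex][1], ")", call. = FALSE)
  }
  statuses <- c("molecular", "clinical", "suspected", "unaffected", "relative")
  ok_st <- df$diagnosis_status %in% statuses
  if (!all(ok_st)) {
    stop("unknown diagnosis_status '", df$diagnosis_status[!ok_st][1], "'",
         call. = FALSE)
  }
  if (!"family_id" %in% names(df)) df$family_id <- NA_character_
  rel_no_fam <- df$diagnosis_status == "relative" & is.na(df$family_id)
  if (any(rel_no_fam)) {
    stop("relative subjects must have a family_id (subject ",
         df$subject_id[rel_no_fam][1], ")", call. = FALSE)
  }
  for (col in c("camera", "race", "ethnicity")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  tibble::as_tibble(df)
}

#' Symmetry pairing of bilateral landmarks
#'
#' Describes the bilateral structure of a landmark template: `pairs` is a
#' two-column matrix of (left, right) landmark indices and `midline` holds
#' the unpaired (mid-sagittal) indices. Together they must partition
#' `1..k`.
#'
#' @param pairs two-column integer matrix of paired landmark indices.
#' @param midline integer vector of midline landmark indices.
#' @param k total number of landmarks.
#' @return An object of class `symmetry_pairing`.
#' @export
symmetry_pairing <- function(pairs, midline = integer(), k = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  all_idx <- c(as.vector(pairs), midline)
  if (anyDuplicated(all_idx)) {
    stop("symmetry pairing repeats landmark index ",
         all_idx[duplicated(all_idx)][1], call. = FALSE)
  }
  if (is.null(k)) k <- max(all_idx)
  if (!setequal(all_idx, seq_len(k))) {
    stop("pairs and midline must partition 1..", k, call. = FALSE)
  }
  structure(list(pairs = pairs, midline = midline, k = k),
            class = "symmetry_pairing")
}

#' @export
print.symmetry_pairing <- function(x, ...) {
  cat("<symmetry_pairing> ", nrow(x$pairs), " bilateral pairs, ",
      length(x$midline), " midline landmarks\n", sep = "")
  invisible(x)
}

#' Read a symmetry pairing from CSV
#'
#' Expects columns `left` and `right`; rows with an empty `right` entry are
#' midline singletons. Indices are 1-based.
#'
#' @param path path to the pairing CSV.
#' @param k total number of landmarks (defaults to the largest index seen).
#' @return A [symmetry_pairing()].
#' @export
read_pairing_csv <- function(path, k = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("left", "right") %in% names(df))) {
    stop("pairing CSV needs columns 'left' and 'right'", call. = FALSE)
  }
  mid <- df$left[is.na(df$right)]
  prs <- df[!is.na(df$right), c("left", "right")]
  symmetry_pairing(as.matrix(prs), midline = mid, k = k)
}

#' Write a symmetry pairing to CSV
#'
#' @param pairing a [symmetry_pairing()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairing_csv <- function(pairing, path) {
  df <- tibble::tibble(
    left = c(pairing$pairs[, 1], pairing$midline),
    right = c(pairing$pairs[, 2], rep(NA_integer_, length(pairing$midline)))
  )
  readr::write_csv(df, path)
  invisible(path)
}
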