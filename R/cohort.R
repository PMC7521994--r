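#' Assemble a cohort from landmarks and metadata
#'
#' Inner-joins landmark configurations and metadata on `subject_id`.
#' Subjects present on only one side are dropped with a message.
#'
#' @param configs a [landmark_set()].
#' @param metadata a metadata tibble (see [read_metadata_csv()]).
#' @param pairing optional [symmetry_pairing()].
#' @return An object of class `cohort`: landmarks, metadata and pairing.
#' @export
assemble_cohort <- function(configs, metadata, pairing = NULL) {
  metadata <- validate_metadata(metadata)
  common <- intersect(configs$subject_id, metadata$subject_id)
  if (length(common) == 0L) {
    stop("no overlapping subject_id between landmarks and metadata",
         call. = FALSE)
  }
  only_lm <- setdiff(configs$subject_id, common)
  only_md <- setdiff(metadata$subject_id, common)
  if (length(only_lm) || length(only_md)) {
    message("assemble_cohort: excluding ", length(only_lm),
            " subject(s) without metadata and ", length(only_md),
            " without landmarks")
  }
  keep <- match(common, configs$subject_id)
  lm <- landmark_set(configs$coords[, , keep, drop = FALSE],
                     configs$subject_id[keep])
  md <- metadata[match(common, metadata$subject_id), ]
  if (!is.null(pairing)) {
    stopifnot(inherits(pairing, "symmetry_pairing"))
    if (pairing$k != n_landmarks(lm)) {
      stop("pairing covers ", pairing$k, " landmarks but configurations have ",
           n_landmarks(lm), call. = FALSE)
    }
  }
  structure(list(landmarks = lm, metadata = md, pairing = pairing),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  syn <- x$metadata$syndrome[x$metadata$diagnosis_status != "relative"]
  cat("<cohort> ", length(x$landmarks), " subjects, ",
      n_landmarks(x$landmarks), " landmarks, ",
      length(unique(setdiff(syn, "unaffected"))), " syndromes, ",
      sum(x$metadata$diagnosis_status == "relative"), " relatives\n", sep = "")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$landmarks)

#' Drop syndromes below a minimum sample size
#'
#' Retains subjects whose syndrome has at least `min_n` non-relative
#' subjects. The reserved `"unaffected"` class and its subjects are always
#' retained; relatives are retained whenever their family syndrome survives.
#'
#' @param cohort a `cohort`.
#' @param min_n minimum per-syndrome sample size (the classification analyses
#'   use 10).
#' @return The filtered `cohort`, with attribute `"dropped"` listing removed
#'   syndrome labels.
#' @export
filter_min_class_size <- function(cohort, min_n = 10) {
  stopifnot(min_n >= 1)
  md <- cohort$metadata
  core <- md$diagnosis_status != "relative" & md$syndrome != "unaffected"
  counts <- table(md$syndrome[core])
  dropped <- names(counts)[counts < min_n]
  keep <- md$syndrome == "unaffected" | !(md$syndrome %in% dropped)
  out <- subset_cohort(cohort, which(keep))
  attr(out, "dropped") <- dropped
  out
}

subset_cohort <- function(cohort, idx) {
  lm <- landmark_set(cohort$landmarks$coords[, , idx, drop = FALSE],
                     cohort$landmarks$subject_id[idx])
  structure(list(landmarks = lm, metadata = cohort$metadata[idx, ],
                 pairing = cohort$pairing),
            class = "cohort")
}
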