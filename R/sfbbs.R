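#' Short Form Berg Balance Scale record
#'
#' The SFBBS rates seven balance items (sitting to standing, standing with
#' eyes closed, reaching forward, picking an object off the floor, turning
#' to look behind, standing feet in line, single-leg stance), each scored
#' 0, 2 or 4, for a total of at most 28. Higher scores indicate better
#' balance; the total is the regression target of this package.
#'
#' @param items numeric vector of 7 item scores, each in {0, 2, 4}.
#' @return Object of class `sfbbs_record` with elements `items` and `total`.
#' @export
sfbbs_record <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 7L)
    abort_argument("SFBBS has exactly 7 items")
  if (!all(items %in% c(0, 2, 4)))
    abort_argument("each SFBBS item score must be 0, 2 or 4")
  structure(list(items = items, total = sum(items)), class = "sfbbs_record")
}

#' @export
print.sfbbs_record <- function(x, ...) {
  cat(sprintf("<sfbbs_record> items [%s], total %d/28\n",
              paste(x$items, collapse = " "), as.integer(x$total)))
  invisible(x)
}

#' Binarize an SFBBS item score into a balance-risk label
#'
#' Item scores 0 and 2 map to the High-risk (positive) class, score 4 to
#' Low-risk. Vectorized.
#'
#' @param item_score vector of item scores in {0, 2, 4}.
#' @return Integer vector: 1 = High-risk, 0 = Low-risk, with attribute
#'   `positive = "High-risk"`.
#' @export
binarize_subtask <- function(item_score) {
  if (!all(item_score %in% c(0, 2, 4)))
    abort_argument("item scores must be 0, 2 or 4")
  structure(as.integer(item_score < 4), positive = "High-risk")
}

#' Participant record
#'
#' Bundles one participant's demographics, TUG recording and (optionally,
#' absent at prediction time) SFBBS scores.
#'
#' @param id opaque identifier.
#' @param age age in years (> 0).
#' @param gender 0 = male, 1 = female.
#' @param recording a [tug_recording()].
#' @param sfbbs optional [sfbbs_record()].
#' @return Object of class `participant_record`.
#' @export
participant_record <- function(id, age, gender, recording, sfbbs = NULL) {
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    abort_argument("age must be a positive number")
  if (!gender %in% c(0, 1))
    abort_argument("gender must be coded 0 (male) or 1 (female)")
  stopifnot(inherits(recording, "tug_recording"))
  if (!is.null(sfbbs)) stopifnot(inherits(sfbbs, "sfbbs_record"))
  structure(list(id = as.character(id), age = as.numeric(age),
                 gender = as.numeric(gender), recording = recording,
                 sfbbs = sfbbs),
            class = "participant_record")
}
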