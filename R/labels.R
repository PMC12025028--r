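#' Gesture label taxonomy
#'
#' Pouring gestures are labelled by fine ids 1--14: 1--4 are left pouring at
#' ascending angle (22.5, 45, 67.5, 90 degrees), 6--9 right pouring, 11--14
#' front pouring, and 5 is the static bottle-grip "hold" class (fine id 10 is
#' an alias of 5 and is normalised on input). Three granularity levels are
#' supported:
#' \describe{
#'   \item{coarse}{4 classes: the pouring directions plus hold.}
#'   \item{granular2}{7 classes: each direction split into a low-angle
#'     \{22.5, 45\} and a high-angle \{67.5, 90\} granule, plus hold.}
#'   \item{granular1}{13 classes: every direction x angle pair, plus hold.}
#' }
#' Class indices are contiguous 1..K with direction blocks ordered
#' left, right, front, hold at every level.
#'
#' @name gesture-labels
NULL

POUR_DIRECTIONS <- c("left", "right", "front", "hold")
POUR_ANGLES <- c(22.5, 45, 67.5, 90)
GRANULARITY_LEVELS <- c("coarse", "granular2", "granular1")

#' Number of classes at a granularity level
#' @param level one of `"coarse"`, `"granular2"`, `"granular1"`.
#' @return integer class count (4, 7 or 13).
#' @export
n_classes <- function(level) {
  level <- match.arg(level, GRANULARITY_LEVELS)
  c(coarse = 4L, granular2 = 7L, granular1 = 13L)[[level]]
}

#' Normalise a fine label id
#'
#' Fine id 10 is an alias of the hold class (5) and is mapped to 5; all other
#' ids pass through unchanged after validation.
#'
#' @param fine_id integer vector of fine ids in 1..14.
#' @return integer vector with 10 replaced by 5.
#' @export
normalize_fine_id <- function(fine_id) {
  fine_id <- as.integer(fine_id)
  if (any(is.na(fine_id)) || any(fine_id < 1L | fine_id > 14L)) {
    stop("fine_id must be an integer in 1..14", call. = FALSE)
  }
  fine_id[fine_id == 10L] <- 5L
  fine_id
}

#' Build a gesture label from its parts
#'
#' @param direction `"left"`, `"right"`, `"front"` or `"hold"`.
#' @param angle pouring angle in degrees (22.5, 45, 67.5 or 90); must be
#'   `NA` for hold.
#' @return a one-row data frame with columns `fine_id`, `direction`, `angle`.
#' @export
gesture_label <- function(direction, angle = NA_real_) {
  direction <- match.arg(direction, POUR_DIRECTIONS)
  if (direction == "hold") {
    if (!is.na(angle)) stop("hold carries no angle", call. = FALSE)
    return(data.frame(fine_id = 5L, direction = "hold", angle = NA_real_))
  }
  if (is.na(angle) || !angle %in% POUR_ANGLES) {
    stop("angle must be one of 22.5, 45, 67.5, 90 for pouring directions",
         call. = FALSE)
  }
  base <- c(left = 0L, right = 5L, front = 10L)[[direction]]
  data.frame(fine_id = base + match(angle, POUR_ANGLES),
             direction = direction, angle = angle)
}

#' Full label table
#'
#' @return data frame with one row per fine id (13 rows; the alias id 10 is
#'   not listed) and columns `fine_id`, `direction`, `angle`, plus the class
#'   index at each granularity level (`coarse_idx`, `granular2_idx`,
#'   `granular1_idx`).
#' @export
label_table <- function() {
  rows <- do.call(rbind, c(
    lapply(POUR_ANGLES, function(a) gesture_label("left", a)),
    lapply(POUR_ANGLES, function(a) gesture_label("right", a)),
    lapply(POUR_ANGLES, function(a) gesture_label("front", a)),
    list(gesture_label("hold"))
  ))
  rows$coarse_idx <- granulate(rows$fine_id, "coarse")
  rows$granular2_idx <- granulate(rows$fine_id, "granular2")
  rows$granular1_idx <- granulate(rows$fine_id, "granular1")
  rows[order(rows$fine_id), , drop = FALSE]
}

.direction_of <- function(fine_id) {
  out <- rep(NA_character_, length(fine_id))
  out[fine_id %in% 1:4] <- "left"
  out[fine_id == 5L] <- "hold"
  out[fine_id %in% 6:9] <- "right"
  out[fine_id %in% 11:14] <- "front"
  out
}

.angle_of <- function(fine_id) {
  # position within a direction block: ids 1-4, 6-9, 11-14 all map to 1-4
  out <- rep(NA_real_, length(fine_id))
  pos <- fine_id %in% c(1:4, 6:9, 11:14)
  block_start <- c(0L, 5L, 10L)[findInterval(fine_id[pos], c(1, 6, 11))]
  out[pos] <- POUR_ANGLES[fine_id[pos] - block_start]
  out
}

#' Map gesture labels to class indices at a granularity level
#'
#' Granulation splits each pouring direction into angle subclasses
#' (granular1: four per direction; granular2: two angle groups,
#' \{22.5, 45\} and \{67.5, 90\}) while hold stays a singleton granule.
#'
#' @param fine_id integer vector of fine ids (1..14; 10 aliases 5).
#' @param level `"coarse"` (4 classes), `"granular2"` (7) or
#'   `"granular1"` (13).
#' @return integer class indices in 1..K.
#' @export
granulate <- function(fine_id, level) {
  level <- match.arg(level, GRANULARITY_LEVELS)
  fine_id <- normalize_fine_id(fine_id)
  dir <- .direction_of(fine_id)
  ang <- .angle_of(fine_id)
  dir_block <- match(dir, POUR_DIRECTIONS) # 1..4 in (left, right, front, hold)
  switch(level,
    coarse = dir_block,
    granular2 = {
      idx <- integer(length(fine_id))
      hold <- dir == "hold"
      grp <- ifelse(ang <= 45, 1L, 2L)
      idx[!hold] <- (dir_block[!hold] - 1L) * 2L + grp[!hold]
      idx[hold] <- 7L
      idx
    },
    granular1 = {
      idx <- integer(length(fine_id))
      hold <- dir == "hold"
      idx[!hold] <- (dir_block[!hold] - 1L) * 4L + match(ang[!hold], POUR_ANGLES)
      idx[hold] <- 13L
      idx
    }
  )
}

.level_rank <- function(level) match(level, GRANULARITY_LEVELS) # coarse=1 .. granular1=3

#' Granule-membership matrix between two levels
#'
#' @param from_level finer level, @param to_level coarser (or equal) level.
#' @return 0/1 matrix G of shape K_to x K_from; `G[i, j] = 1` iff fine class
#'   j coarsens into class i.
#' @export
granule_matrix <- function(from_level, to_level) {
  from_level <- match.arg(from_level, GRANULARITY_LEVELS)
  to_level <- match.arg(to_level, GRANULARITY_LEVELS)
  if (.level_rank(from_level) < .level_rank(to_level)) {
    stop("cannot coarsen from ", to_level, " to the finer ", from_level,
         ": granulation is not invertible", call. = FALSE)
  }
  ids <- unique(normalize_fine_id(1:14))
  from_idx <- granulate(ids, from_level)
  to_idx <- granulate(ids, to_level)
  G <- matrix(0L, n_classes(to_level), n_classes(from_level))
  G[cbind(to_idx, from_idx)] <- 1L
  G
}

#' Coarsen class indices between granularity levels
#'
#' Deterministic surjection mapping subclasses back to their primary (or
#' intermediate) categories; satisfies
#' `coarsen(granulate(y, from), from, to) == granulate(y, to)` for every
#' label y.
#'
#' @param class_idx integer class indices at `from_level` (1..K_from).
#' @param from_level,to_level granularity levels; `from_level` must be at
#'   least as fine as `to_level`.
#' @return integer class indices at `to_level`.
#' @export
coarsen <- function(class_idx, from_level, to_level) {
  G <- granule_matrix(from_level, to_level)
  class_idx <- as.integer(class_idx)
  if (any(is.na(class_idx)) || any(class_idx < 1L | class_idx > ncol(G))) {
    stop("class index out of range for level ", from_level, call. = FALSE)
  }
  map <- apply(G, 2, which.max)
  map[class_idx]
}

#' Coarsen a probability vector (or matrix) over fine classes
#'
#' The coarse probability of a class is the sum of the probabilities of its
#' member granules (probability-mass summation, not argmax-then-map).
#'
#' @param p numeric vector of length K_from summing to 1, or a matrix with
#'   one such row per observation.
#' @param from_level,to_level granularity levels as in [coarsen()].
#' @return probability vector (or matrix) over the coarse classes.
#' @export
coarsen_probabilities <- function(p, from_level, to_level) {
  G <- granule_matrix(from_level, to_level)
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, nrow = 1) else as.matrix(p)
  if (ncol(pm) != ncol(G)) {
    stop("probability vector length ", ncol(pm), " does not match ",
         from_level, " (", ncol(G), " classes)", call. = FALSE)
  }
  if (any(!is.finite(pm)) || any(pm < -1e-9) ||
      any(abs(rowSums(pm) - 1) > 1e-6)) {
    stop("p must be a probability vector summing to 1", call. = FALSE)
  }
  out <- pm %*% t(G)
  if (vec) drop(out) else out
}

#' Export the label map as a data frame (CSV-ready)
#'
#' @param path optional file path; when given the table is written as CSV.
#' @return the label map data frame, invisibly when written to file.
#' @export
write_label_map <- function(path = NULL) {
  tab <- label_table()
  tab <- tab[, c("fine_id", "direction", "angle",
                 "granular1_idx", "granular2_idx", "coarse_idx")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
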