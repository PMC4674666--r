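#' Construct a clutch observation
#'
#' A clutch observation is one photographed state of a nest: the nest
#' identifier, the phase (before or after the experimental manipulation),
#' the annotated nest-cup center, and one annotation row per egg giving the
#' image coordinates of its blunt and sharp poles.
#'
#' Coordinates follow the image convention (origin top-left, x right,
#' y down, units of pixels). All angular metrics convert to mathematical
#' y-up coordinates internally, so that "angle from the positive x axis"
#' reads conventionally (counter-clockwise positive in the y-up frame).
#'
#' @param nest_id character or integer nest identifier.
#' @param phase `"before"` or `"after"`.
#' @param center numeric length-2, nest-center pixel coordinates `(x, y)`.
#' @param eggs data.frame with columns `egg_id`, `blunt_x`, `blunt_y`,
#'   `sharp_x`, `sharp_y`, `is_model_egg` (logical). One row per egg.
#' @param px_per_mm optional scale factor (pixels per millimetre).
#'
#' @return An object of class `clutch_observation`.
#' @export
clutch_observation <- function(nest_id, phase = c("before", "after"),
                               center, eggs, px_per_mm = NULL) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  eggs <- as.data.frame(eggs)
  req <- c("egg_id", "blunt_x", "blunt_y", "sharp_x", "sharp_y", "is_model_egg")
  missing_cols <- setdiff(req, names(eggs))
  if (length(missing_cols))
    stop("egg table lacks columns: ", paste(missing_cols, collapse = ", "))
  coords <- as.matrix(eggs[, c("blunt_x", "blunt_y", "sharp_x", "sharp_y")])
  if (!all(is.finite(coords)))
    stop("non-finite egg coordinates")
  if (any(eggs$blunt_x == eggs$sharp_x & eggs$blunt_y == eggs$sharp_y))
    stop("degenerate egg: blunt pole coincides with sharp pole")
  if (anyDuplicated(eggs$egg_id))
    stop("egg_id values must be unique within an observation")
  eggs$is_model_egg <- as.logical(eggs$is_model_egg)
  n_host <- sum(!eggs$is_model_egg)
  if (n_host < 1) stop("observation contains no host eggs")
  structure(
    list(nest_id = nest_id, phase = phase,
         center = as.numeric(center), eggs = eggs,
         px_per_mm = px_per_mm),
    class = "clutch_observation")
}

#' @export
print.clutch_observation <- function(x, ...) {
  cat(sprintf("<clutch_observation> nest %s, phase %s: %d host egg(s)%s\n",
              as.character(x$nest_id), x$phase,
              sum(!x$eggs$is_model_egg),
              if (any(x$eggs$is_model_egg)) " + 1 model egg" else ""))
  invisible(x)
}

host_eggs <- function(obs) obs$eggs[!obs$eggs$is_model_egg, , drop = FALSE]

#' Read per-egg annotations from CSV
#'
#' Expects one row per egg per phase with columns `nest_id`, `phase`,
#' `egg_id`, `is_model_egg`, `blunt_x`, `blunt_y`, `sharp_x`, `sharp_y`,
#' `center_x`, `center_y` and optionally `px_per_mm`.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return A list of [clutch_observation()] objects, one per
#'   (nest_id, phase) combination.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("nest_id", "phase", "egg_id", "is_model_egg",
           "blunt_x", "blunt_y", "sharp_x", "sharp_y",
           "center_x", "center_y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  keys <- unique(df[, c("nest_id", "phase")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$nest_id == keys$nest_id[i] & df$phase == keys$phase[i], ]
    clutch_observation(
      nest_id = keys$nest_id[i], phase = keys$phase[i],
      center = c(sub$center_x[1], sub$center_y[1]),
      eggs = sub[, c("egg_id", "blunt_x", "blunt_y",
                     "sharp_x", "sharp_y", "is_model_egg")],
      px_per_mm = if ("px_per_mm" %in% names(sub)) sub$px_per_mm[1] else NULL)
  })
}

#' Write clutch observations to an annotation CSV
#'
#' @param observations a list of [clutch_observation()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(observations, path) {
  rows <- lapply(observations, function(obs) {
    e <- obs$eggs
    data.frame(nest_id = obs$nest_id, phase = obs$phase,
               egg_id = e$egg_id, is_model_egg = e$is_model_egg,
               blunt_x = e$blunt_x, blunt_y = e$blunt_y,
               sharp_x = e$sharp_x, sharp_y = e$sharp_y,
               center_x = obs$center[1], center_y = obs$center[2],
               px_per_mm = if (is.null(obs$px_per_mm)) NA_real_ else obs$px_per_mm)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
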