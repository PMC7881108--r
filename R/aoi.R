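#' Area-of-interest codes and labels
#'
#' The driving scene is partitioned into seven dynamic areas of interest
#' (AOIs), coded 0 to 6. The coding is fixed: 0 = speedometer (SF),
#' 1 = leading vehicle (LVF), 2 = near road between the driven and the
#' leading vehicle (NF), 3 = road section around the leading vehicle (GF),
#' 4 = far road beyond the leading vehicle (LAF), 5 = left scenery,
#' 6 = right scenery (RSF).
#'
#' @return A named character vector of length 7; names are the codes
#'   `"0"`..`"6"`, values are the labels.
#' @examples
#' aoi_labels()
#' @export
aoi_labels <- function() {
  c(`0` = "speedometer", `1` = "leading_vehicle", `2` = "near_road",
    `3` = "road_around_leader", `4` = "far_road", `5` = "left_scenery",
    `6` = "right_scenery")
}

#' Functional scan-path classes
#'
#' The six functional classes of the taxonomy, in their canonical order:
#' forward polling (trajectory planning), guidance (steering control),
#' backwards polling (stabilising control / headway monitoring), right
#' scenery, speed monitoring, and supervision (automation monitoring,
#' assignable only under highly automated driving or by triplet-catalogue
#' membership).
#'
#' @return Character vector of the six class names.
#' @examples
#' scanpath_classes()
#' @export
scanpath_classes <- function() {
  c("forward_polling", "guidance", "backwards_polling",
    "right_scenery", "speed_monitoring", "supervision")
}

# valid AOI codes as integers
aoi_codes <- function() 0:6

# "1214" -> c(1L, 2L, 1L, 4L); validates digits and adjacency
sp_codes <- function(x) {
  v <- suppressWarnings(as.integer(strsplit(x, "", fixed = TRUE)[[1]]))
  if (anyNA(v) || !all(v %in% aoi_codes()))
    stop("scan path '", x, "' contains a code outside 0-6", call. = FALSE)
  if (length(v) >= 2 && any(v[-1] == v[-length(v)]))
    stop("scan path '", x, "' has an immediate AOI repeat", call. = FALSE)
  v
}

sp_string <- function(v) paste(v, collapse = "")

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
}
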