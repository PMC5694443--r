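check_ordinal <- function(x, hi, what) {
  bad <- !is.na(x) & (x < 0 | x > hi | x != floor(x))
  if (any(bad)) {
    stop_validation("%s must be integers in [0, %d]; offending values: %s",
                    what, hi, paste(unique(x[bad]), collapse = ", "))
  }
  invisible(x)
}

#' Total arthritis score of one animal-day
#'
#' Each hind paw is scored on the 0-4 redness/swelling rubric; the per-day
#' total is their sum (0-8).  Front paws are not scored.
#'
#' @param left,right Hind-paw scores, integers in 0-4 (vectorised; NA if a
#'   paw was not scored).
#' @return Integer total in 0-8 (`NA` if either paw is missing).
#' @examples
#' total_arthritis_score(3, 4)  # 7
#' @export
total_arthritis_score <- function(left, right) {
  check_ordinal(left, 4L, "paw scores")
  check_ordinal(right, 4L, "paw scores")
  left + right
}

#' Total histopathology score for one ankle
#'
#' Five subscores (degree of inflammation, pannus formation, cartilage
#' damage, bone resorption, periosteal bone formation), each 0-5, summed
#' for a maximum total of 25.
#'
#' @param inflammation,pannus,cartilage_damage,bone_resorption,periosteal_bone
#'   Subscores, integers in 0-5 (vectorised).
#' @return Integer side total in 0-25.
#' @examples
#' histopath_total(5, 5, 5, 5, 5)  # 25
#' @export
histopath_total <- function(inflammation, pannus, cartilage_damage,
                            bone_resorption, periosteal_bone) {
  args <- list(inflammation = inflammation, pannus = pannus,
               cartilage_damage = cartilage_damage,
               bone_resorption = bone_resorption,
               periosteal_bone = periosteal_bone)
  for (nm in names(args)) check_ordinal(args[[nm]], 5L, paste(nm, "subscores"))
  inflammation + pannus + cartilage_damage + bone_resorption + periosteal_bone
}

#' Per-animal histopathology score
#'
#' Left and right tibiotarsal joints are scored separately and the mean of
#' the two side totals is the animal's score.  If only one side was scored
#' (e.g. an early-euthanised animal), the available side is used and a
#' message is logged rather than failing.
#'
#' @param left_total,right_total Side totals, integers in 0-25 (vectorised;
#'   NA = side not scored).
#' @return Mean histopathology score per animal.
#' @examples
#' animal_histopath(10, 6)  # 8
#' @export
animal_histopath <- function(left_total, right_total) {
  check_ordinal(left_total, 25L, "side totals")
  check_ordinal(right_total, 25L, "side totals")
  one_sided <- xor(is.na(left_total), is.na(right_total))
  if (any(one_sided)) {
    message(sprintf("%d animal(s) scored on one side only; using that side",
                    sum(one_sided)))
  }
  out <- (left_total + right_total) / 2
  out[one_sided] <- pmax(left_total, right_total, na.rm = TRUE)[one_sided]
  out
}

#' Per-day joint size of an animal
#'
#' The single joint-size series used for thresholding is the maximum of the
#' left and right ankle measurements; a missing side falls back to the
#' measured one.
#'
#' @param left,right Ankle sizes in inches (vectorised).
#' @return Maximum available size per day (`NA` if neither side measured).
#' @examples
#' max_joint_size(0.24, 0.28)  # 0.28
#' @export
max_joint_size <- function(left, right) {
  out <- pmax(left, right, na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Per-animal mean histopathology totals from a side-level table
#'
#' @param histopath Tibble with columns `animal_id`, `side`, and the five
#'   subscore columns.
#' @return Tibble with per-animal means of the five subscores and of the
#'   side total (`histo_total`).
#' @export
histopath_summary <- function(histopath) {
  histopath$side_total <- histopath_total(
    histopath$inflammation, histopath$pannus, histopath$cartilage_damage,
    histopath$bone_resorption, histopath$periosteal_bone)
  histopath |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(dplyr::across(c("inflammation", "pannus", "cartilage_damage",
                                     "bone_resorption", "periosteal_bone"),
                                   mean),
                     histo_total = mean(.data$side_total), .groups = "drop")
}
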