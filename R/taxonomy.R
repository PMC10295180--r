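#' Cattle action taxonomy
#'
#' The eleven annotated cattle actions and their categories. *Individual*
#' actions describe the whole body of one animal and are the labels carried
#' through tracking; *part* actions are localized to a body part (head, mouth,
#' tail) and are attributed to an individual for statistics; *group* actions
#' involve more than one animal and are surfaced as alerts only -- they never
#' enter the tracker.
#'
#' @return A data frame with columns `action` (character) and `category`
#'   (factor with levels `individual`, `part`, `group`), one row per action,
#'   in canonical order.
#' @examples
#' action_taxonomy()
#' individual_actions()
#' @export
action_taxonomy <- function() {
  data.frame(
    action = c(
      "standing", "walking", "resting", "standing up", "self-grooming",
      "moving head", "ruminating", "tail wagging",
      "social licking", "fighting", "feeding"
    ),
    category = factor(
      rep(c("individual", "part", "group"), times = c(5L, 3L, 3L)),
      levels = c("individual", "part", "group")
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname action_taxonomy
#' @export
individual_actions <- function() {
  tx <- action_taxonomy()
  tx$action[tx$category == "individual"]
}

#' @rdname action_taxonomy
#' @export
part_actions <- function() {
  tx <- action_taxonomy()
  tx$action[tx$category == "part"]
}

#' @rdname action_taxonomy
#' @export
group_actions <- function() {
  tx <- action_taxonomy()
  tx$action[tx$category == "group"]
}

#' @rdname action_taxonomy
#' @param actions character vector of action labels to look up.
#' @export
action_category <- function(actions) {
  tx <- action_taxonomy()
  idx <- match(actions, tx$action)
  if (anyNA(idx)) {
    stop("unknown action label(s): ",
         paste(unique(actions[is.na(idx)]), collapse = ", "))
  }
  as.character(tx$category[idx])
}
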