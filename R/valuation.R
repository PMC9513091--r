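# Subjective valuation: monetary-equivalence ratings -> per-unit values.

#' Per-unit subjective value from monetary-equivalence ratings
#'
#' Participants state the quantity of an item they judge equivalent to
#' gaining (reward) or losing (effort, punishment) 1 euro (`q1`) and
#' 5 euros (`q5`). The per-euro quantity is the average of the two
#' ratings after scaling the 5-euro rating down, `Q = (q1 + q5/5) / 2`,
#' and the per-unit value is its reciprocal `1/Q` (euros per unit).
#'
#' The averaging convention is ambiguous between averaging per-euro
#' *quantities* and then inverting (default, `method = "quantity"`) and
#' averaging the two implied per-unit *euro* values `1/q1` and `5/q5`
#' (`method = "euro"`). Both are provided; they agree whenever the two
#' ratings are self-consistent (`q5 = 5 q1`).
#'
#' @param q1,q5 positive numeric vectors: quantities judged equivalent to
#'   1 and 5 euros.
#' @param method `"quantity"` (average per-euro quantities, then invert)
#'   or `"euro"` (average the two implied euro-per-unit values).
#' @return numeric vector of per-unit values in euros per unit.
#' @examples
#' unit_value(1, 5)    # self-consistent rating -> 1 euro/unit
#' unit_value(2, 12)   # Q = 2.2 -> 0.4545 euro/unit
#' @export
unit_value <- function(q1, q5, method = c("quantity", "euro")) {
  method <- match.arg(method)
  if (any(!is.finite(q1)) || any(!is.finite(q5)) || any(q1 <= 0) || any(q5 <= 0)) {
    stop("rating quantities must be positive and finite", call. = FALSE)
  }
  if (method == "quantity") {
    1 / ((q1 + q5 / 5) / 2)
  } else {
    (1 / q1 + 5 / q5) / 2
  }
}

#' Unit values for a table of item ratings
#'
#' @param ratings data frame with columns `participant_id`, `item_id`,
#'   `category`, `q1`, `q5` (see [read_ratings()]).
#' @inheritParams unit_value
#' @return data frame `participant_id`, `item_id`, `category`,
#'   `value_per_unit` (euros per unit).
#' @export
unit_values_from_ratings <- function(ratings, method = c("quantity", "euro")) {
  method <- match.arg(method)
  required <- c("participant_id", "item_id", "category", "q1", "q5")
  missing <- setdiff(required, names(ratings))
  if (length(missing)) {
    stop_config("ratings table is missing column(s): ", paste(missing, collapse = ", "))
  }
  data.frame(
    participant_id = ratings$participant_id,
    item_id = ratings$item_id,
    category = ratings$category,
    value_per_unit = unit_value(ratings$q1, ratings$q5, method = method),
    stringsAsFactors = FALSE
  )
}

#' Undiscounted option value
#'
#' Linear scaling: the value (or cost) of an option offering `quantity`
#' units of an item is the quantity times the item's per-unit value.
#'
#' @param quantity nonnegative numeric vector, number of units on offer.
#' @param unit_value per-unit value in euros (from [unit_value()]).
#' @return option value in euros.
#' @export
option_value_undiscounted <- function(quantity, unit_value) {
  if (any(quantity < 0, na.rm = TRUE)) {
    stop("`quantity` must be nonnegative", call. = FALSE)
  }
  quantity * unit_value
}
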