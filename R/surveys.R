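#' Survey response containers
#'
#' Item-level responses for the three user-experience instruments:
#' SUS (10 items, 1-5), QUEST (12 items, 1-5, plus exactly 3
#' most-important-item picks) and IMI (37 items, 1-7, six subscales).
#' Constructors validate item counts and ranges; scoring refuses
#' out-of-range input rather than clamping.
#'
#' @param items Integer vector of item responses.
#' @param importance_picks For QUEST: character vector of exactly 3
#'   distinct item labels drawn from `quest_item_labels()`.
#' @return An object of class `sus_response`, `quest_response` or
#'   `imi_response`.
#' @name survey_response
NULL

check_items <- function(items, n, lo, hi, what) {
  if (length(items) != n)
    stop(sprintf("%s requires exactly %d items, got %d", what, n, length(items)))
  if (anyNA(items)) stop(sprintf("%s has missing items", what))
  if (any(items != round(items)) || any(items < lo) || any(items > hi))
    stop(sprintf("%s items must be integers in %d..%d", what, lo, hi))
  as.integer(items)
}

#' @rdname survey_response
#' @export
sus_response <- function(items) {
  structure(list(items = check_items(items, 10L, 1L, 5L, "SUS")),
            class = "sus_response")
}

#' @rdname survey_response
#' @export
quest_response <- function(items, importance_picks = NULL) {
  items <- check_items(items, 12L, 1L, 5L, "QUEST")
  if (!is.null(importance_picks)) {
    importance_picks <- as.character(importance_picks)
    if (length(importance_picks) != 3L || anyDuplicated(importance_picks))
      stop("importance_picks must be exactly 3 distinct labels")
    bad <- setdiff(importance_picks, quest_item_labels())
    if (length(bad))
      stop("unknown QUEST item label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(items = items, importance_picks = importance_picks),
            class = "quest_response")
}

#' @rdname survey_response
#' @export
imi_response <- function(items) {
  structure(list(items = check_items(items, 37L, 1L, 7L, "IMI")),
            class = "imi_response")
}

#' QUEST item labels
#'
#' The 12 satisfaction items (8 device + 4 services) from which each
#' respondent also selects the 3 of most importance.
#'
#' @return Character vector of length 12.
#' @export
quest_item_labels <- function() {
  c("dimensions", "weight", "adjustments", "safety", "durability",
    "ease_of_use", "comfort", "effectiveness", "service_delivery",
    "troubleshooting", "professional_services", "follow_up_services")
}

#' Default IMI item-to-subscale map and reverse-item set
#'
#' The 37-item motivation inventory spans six subscales; this default map
#' assigns items 1-7 to interest/enjoyment, 8-12 to effort/importance,
#' 13-19 to value/usefulness, 20-26 to perceived choice, 27-32 to
#' perceived competence and 33-37 to pressure/tension (subscale sizes
#' 7/5/7/7/6/5, summing to 37 as in the standard multi-dimensional
#' instrument). The reverse-item set is a repo convention: instruments in
#' the field word some items negatively and score them as `8 - response`.
#' Both are config-driven; check them against the concrete instrument
#' before comparing scores across studies.
#'
#' @return `imi_default_map()`: named integer vector of length 37 mapping
#'   each item to a subscale label. `imi_default_reverse()`: integer
#'   vector of reverse-scored item indices.
#' @export
imi_default_map <- function() {
  rep(c("interest_enjoyment", "effort_importance", "value_usefulness",
        "perceived_choice", "perceived_competence", "pressure_tension"),
      times = c(7L, 5L, 7L, 7L, 6L, 5L))
}

#' @rdname imi_default_map
#' @export
imi_default_reverse <- function() c(6L, 9L, 11L, 21L, 24L, 26L, 33L, 35L)

#' Score the System Usability Scale
#'
#' Standard SUS scoring: odd (positively worded) items contribute
#' `score - 1`, even (negatively worded) items contribute `5 - score`;
#' the sum of contributions is multiplied by 2.5, giving 0-100. A score
#' of 68 is the conventional cut-off for passable usability.
#'
#' @param response A [sus_response()] or a bare integer vector of 10
#'   items in 1-5.
#' @return Numeric score in \[0, 100\].
#' @examples
#' score_sus(rep(3, 10))  # 50
#' @export
score_sus <- function(response) {
  if (inherits(response, "sus_response")) response <- response$items
  items <- check_items(response, 10L, 1L, 5L, "SUS")
  odd <- items[seq(1L, 9L, by = 2L)]
  even <- items[seq(2L, 10L, by = 2L)]
  2.5 * (sum(odd - 1L) + sum(5L - even))
}

#' Score the QUEST satisfaction instrument
#'
#' The QUEST score is the arithmetic mean of the 12 item responses
#' (1-5); the scale midpoint 3 separates positive from negative
#' assessments.
#'
#' @param response A [quest_response()] or bare vector of 12 items.
#' @param na_action `"error"` (default) refuses missing items;
#'   `"mean"` averages the answered items (logged via a warning).
#' @return Numeric score in \[1, 5\].
#' @export
score_quest <- function(response, na_action = c("error", "mean")) {
  na_action <- match.arg(na_action)
  if (inherits(response, "quest_response")) response <- response$items
  if (anyNA(response) && na_action == "mean") {
    n_miss <- sum(is.na(response))
    ok <- response[!is.na(response)]
    check_items(ok, length(ok), 1L, 5L, "QUEST")
    warning(sprintf("QUEST: averaging %d answered items (%d missing)",
                    length(ok), n_miss))
    return(mean(ok))
  }
  mean(check_items(response, 12L, 1L, 5L, "QUEST"))
}

#' Tally QUEST most-important-item selections over a cohort
#'
#' Each respondent picks exactly 3 of the 12 items as most important for
#' determining satisfaction; the tally counts picks per item over the
#' cohort (total = 3 x number of respondents).
#'
#' @param picks A list whose elements are 3-element character vectors of
#'   item labels (or [quest_response()] objects carrying picks).
#' @return Named integer vector over [quest_item_labels()].
#' @export
quest_importance_tally <- function(picks) {
  labels <- quest_item_labels()
  counts <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_along(picks)) {
    p <- picks[[i]]
    if (inherits(p, "quest_response")) p <- p$importance_picks
    if (is.null(p) || length(p) != 3L || anyDuplicated(p))
      stop(sprintf("record %d: exactly 3 distinct importance picks required", i))
    bad <- setdiff(p, labels)
    if (length(bad))
      stop(sprintf("record %d: unknown label(s) %s", i,
                   paste(bad, collapse = ", ")))
    counts[p] <- counts[p] + 1L
  }
  counts
}

#' Score the 37-item motivation inventory (IMI)
#'
#' Reverse-scored items are transformed as `8 - score`, then responses
#' are averaged within each of the six subscales, giving one score in
#' 1-7 per subscale. The scale midpoint 4 is the conventional
#' favourability threshold; pressure/tension is favourable when low.
#'
#' @param response An [imi_response()] or bare vector of 37 items (1-7).
#' @param subscale_map Character vector of length 37 assigning each item
#'   to a subscale; must cover every item exactly once across exactly 6
#'   subscales. Default [imi_default_map()].
#' @param reverse_items Integer indices of reverse-scored items. Default
#'   [imi_default_reverse()].
#' @return Named numeric vector of 6 subscale means in \[1, 7\].
#' @export
score_imi <- function(response, subscale_map = imi_default_map(),
                      reverse_items = imi_default_reverse()) {
  if (inherits(response, "imi_response")) response <- response$items
  items <- check_items(response, 37L, 1L, 7L, "IMI")
  if (length(subscale_map) != 37L || anyNA(subscale_map))
    stop("subscale_map must assign all 37 items")
  if (length(unique(subscale_map)) != 6L)
    stop("subscale_map must define exactly 6 subscales")
  if (length(reverse_items)) {
    if (anyDuplicated(reverse_items) ||
        any(reverse_items < 1L) || any(reverse_items > 37L))
      stop("reverse_items must be distinct indices in 1..37")
    items[reverse_items] <- 8L - items[reverse_items]
  }
  out <- tapply(items, factor(subscale_map, levels = unique(subscale_map)),
                mean)
  stats::setNames(as.numeric(out), names(out))
}
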