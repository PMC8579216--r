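# Self-report instrument scoring. Item-level rules follow the published
# instrument keys: SCARED (33-item version, items 0-2, plain sum), CES-DC
# (20 items, 0-3, positively-worded items 4/8/12/16 reverse-scored as
# 3 - raw), ASRS (18 items, 0-4 frequency sum, used dimensionally). Missing
# items are imputed with the participant's mean over answered items when at
# least 80% of items are answered; otherwise the total is missing.

instrument_specs <- list(
  SCARED33 = list(n_items = 33L, range = c(0L, 2L), reverse = integer(0)),
  CESDC = list(n_items = 20L, range = c(0L, 3L), reverse = c(4L, 8L, 12L, 16L)),
  ASRS = list(n_items = 18L, range = c(0L, 4L), reverse = integer(0))
)

score_items <- function(items, spec, reverse = spec$reverse,
                        min_completeness = 0.8) {
  if (length(items) != spec$n_items) {
    stop_bad_arg("expected %d items, got %d", spec$n_items, length(items))
  }
  answered <- !is.na(items)
  rng <- spec$range
  if (any(items[answered] < rng[1] | items[answered] > rng[2])) {
    stop_bad_arg("item responses must lie in [%d, %d]", rng[1], rng[2])
  }
  vals <- items
  if (length(reverse)) vals[reverse] <- rng[2] - vals[reverse]
  completeness <- mean(answered)
  if (completeness < min_completeness) return(NA_real_)
  if (any(!answered)) vals[!answered] <- mean(vals[answered])
  sum(vals)
}

#' Score the 33-item SCARED anxiety screen
#'
#' Sum of 33 items scored 0-2 (total range 0-66). Items missing for a
#' participant are imputed by that participant's mean over answered items when
#' at least 80% are answered; otherwise the total is `NA`. Which 33 of the
#' instrument's 41 items are administered is the caller's responsibility; the
#' items are summed as supplied.
#'
#' @param items Integer vector of length 33, values in `{0, 1, 2}` or `NA`.
#' @param min_completeness Minimum answered fraction for a valid total.
#' @return Total score (0-66) or `NA`.
#' @export
score_scared <- function(items, min_completeness = 0.8) {
  score_items(items, instrument_specs$SCARED33, min_completeness = min_completeness)
}

#' Score the 20-item CES-DC depression scale
#'
#' Sum of 20 items scored 0-3 (total range 0-60) with the instrument's
#' positively-worded items reverse-scored as `3 - raw` — items 4, 8, 12 and
#' 16 under the standard key, overridable via `reverse` for alternative item
#' orderings. Missingness handling as in [score_scared()].
#'
#' @param items Integer vector of length 20, values in `{0..3}` or `NA`.
#' @param reverse Indices of reverse-keyed items (default `c(4, 8, 12, 16)`).
#' @param min_completeness Minimum answered fraction for a valid total.
#' @return Total score (0-60) or `NA`.
#' @export
score_cesdc <- function(items, reverse = c(4L, 8L, 12L, 16L),
                        min_completeness = 0.8) {
  score_items(items, instrument_specs$CESDC, reverse = reverse,
              min_completeness = min_completeness)
}

#' Score the 18-item ASRS (adult ADHD) scale
#'
#' Plain frequency sum of 18 items scored 0-4 (total range 0-72), used
#' dimensionally as a discriminant-validity comparator. Missingness handling
#' as in [score_scared()].
#'
#' @param items Integer vector of length 18, values in `{0..4}` or `NA`.
#' @param min_completeness Minimum answered fraction for a valid total.
#' @return Total score (0-72) or `NA`.
#' @export
score_asrs <- function(items, min_completeness = 0.8) {
  score_items(items, instrument_specs$ASRS, min_completeness = min_completeness)
}

#' Score a long-format survey table
#'
#' Scores every participant x instrument block of an item-level survey table
#' and returns one row of instrument totals per participant.
#'
#' @param surveys Tibble with `participant_id`, `instrument` (`SCARED33`,
#'   `CESDC`, `ASRS`) and item columns `item_1` ... `item_k` (`k` up to the
#'   longest instrument; trailing items beyond an instrument's length must be
#'   `NA` and are ignored).
#' @param min_completeness Minimum answered fraction for a valid total.
#' @return Tibble: `participant_id`, `scared_total`, `cesdc_total`,
#'   `asrs_total`, and per-instrument completeness columns.
#' @export
score_surveys <- function(surveys, min_completeness = 0.8) {
  item_cols <- grep("^item_\\d+$", names(surveys), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  scorers <- list(SCARED33 = score_scared, CESDC = score_cesdc, ASRS = score_asrs)
  out_col <- c(SCARED33 = "scared", CESDC = "cesdc", ASRS = "asrs")
  bad <- setdiff(unique(surveys$instrument), names(scorers))
  if (length(bad)) stop_bad_arg("unknown instrument(s): %s", paste(bad, collapse = ", "))
  long <- purrr::map_dfr(unique(surveys$instrument), function(ins) {
    sub <- surveys[surveys$instrument == ins, , drop = FALSE]
    k <- instrument_specs[[ins]]$n_items
    m <- as.matrix(sub[, item_cols[seq_len(k)], drop = FALSE])
    totals <- apply(m, 1, scorers[[ins]], min_completeness = min_completeness)
    tibble::tibble(participant_id = sub$participant_id, stem = out_col[[ins]],
                   total = as.numeric(totals),
                   completeness = rowMeans(!is.na(m)))
  })
  long |>
    tidyr::pivot_wider(names_from = "stem",
                       values_from = c("total", "completeness"),
                       names_glue = "{stem}_{.value}")
}
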