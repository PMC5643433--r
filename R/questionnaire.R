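#' Questionnaire scale definitions
#'
#' The 17-item post-session questionnaire combines items from the Igroup
#' Presence Questionnaire, the Presence Questionnaire, the System Usability
#' Scale and the Simulator Sickness Questionnaire, scored on a 1-5 scale
#' and grouped into eight composite scales. Item 17 (favourite video) is a
#' choice item and belongs to no scale. The `direction` column gives the
#' side of the one-sided midpoint test each scale is expected on:
#' usability, immersion, presence, realism and involvement `above` the
#' midpoint; sickness, oculomotor problems and disorientation `below`.
#'
#' @return A data.frame `scale, items (comma-separated item numbers),
#'   direction`.
#' @export
scale_definitions <- function() {
  data.frame(
    scale = c("usability", "sickness", "oculomotor_problems",
              "disorientation", "immersion", "presence", "realism",
              "involvement"),
    items = c("7,8,9", "10,11,12,15", "13,14", "16", "1", "2", "5",
              "3,4,6"),
    direction = c("above", "below", "below", "below", "above", "above",
                  "above", "above"),
    stringsAsFactors = FALSE)
}

parse_items <- function(items) as.integer(strsplit(items, ",")[[1]])

#' Score questionnaire responses into composite scales
#'
#' Each scale score is the unweighted mean of its items. A participant
#' with a missing item gets a missing score on the scales using that item;
#' other scales are unaffected. Responses must lie in `[1, 5]`.
#'
#' @param responses data.frame `participant_id, item_1 .. item_17`.
#' @param definitions scale definitions, see [scale_definitions()].
#' @return A data.frame `participant_id` plus one column per scale.
#' @examples
#' resp <- data.frame(participant_id = 1,
#'                    matrix(3, 1, 17, dimnames = list(NULL,
#'                           paste0("item_", 1:17))))
#' score_scales(resp)
#' @export
score_scales <- function(responses, definitions = scale_definitions()) {
  for (d in seq_len(nrow(definitions))) {
    for (it in parse_items(definitions$items[d])) {
      col <- paste0("item_", it)
      if (!col %in% names(responses))
        stop(sprintf("missing item column '%s'", col), call. = FALSE)
      bad <- which(!is.na(responses[[col]]) &
                     (responses[[col]] < 1 | responses[[col]] > 5))
      if (length(bad))
        stop(sprintf("response out of [1, 5]: item %d, participant %s",
                     it, responses$participant_id[bad[1]]), call. = FALSE)
    }
  }
  out <- data.frame(participant_id = responses$participant_id)
  for (d in seq_len(nrow(definitions))) {
    cols <- paste0("item_", parse_items(definitions$items[d]))
    m <- as.matrix(responses[cols])
    out[[definitions$scale[d]]] <- rowMeans(m)  # NA if any item missing
  }
  out
}

#' One-sided t-test of a scale against the rating-scale midpoint
#'
#' Tests whether scores sit significantly above or below the midpoint of
#' the 1-5 rating scale: `t = (mean - midpoint) / (sd / sqrt(n))` with
#' `n - 1` degrees of freedom and the one-sided p-value on the scale's
#' stated side.
#'
#' @param scores numeric scores for one scale (one per participant).
#' @param midpoint scale midpoint (default 2.5).
#' @param direction `"above"` or `"below"`.
#' @return A data.frame `mean, sd, t, df, p` (one row); `t` and `p` are
#'   `NA`, with a warning, when the scores have zero spread.
#' @export
midpoint_ttest <- function(scores, midpoint = 2.5,
                           direction = c("above", "below")) {
  direction <- match.arg(direction)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2) stop("need at least 2 scores", call. = FALSE)
  m <- mean(scores); s <- sd(scores)
  if (s == 0) {
    warning("zero standard deviation; t undefined", call. = FALSE)
    return(data.frame(mean = m, sd = s, t = NA_real_, df = n - 1,
                      p = NA_real_))
  }
  tt <- midpoint_t_from_summary(m, s, n, midpoint)
  p <- if (direction == "above") pt(tt, n - 1, lower.tail = FALSE)
       else pt(tt, n - 1)
  data.frame(mean = m, sd = s, t = tt, df = n - 1, p = p)
}

#' Midpoint t-statistic from summary statistics
#'
#' @param mean,sd,n sample summary of the scale scores.
#' @param midpoint scale midpoint (default 2.5).
#' @return The t-statistic `(mean - midpoint) / (sd / sqrt(n))`.
#' @export
midpoint_t_from_summary <- function(mean, sd, n, midpoint = 2.5) {
  (mean - midpoint) / (sd / sqrt(n))
}

#' Midpoint tests for all scales
#'
#' @param scores scale-score table from [score_scales()].
#' @param definitions scale definitions (directions are taken from here).
#' @param midpoint scale midpoint.
#' @return A data.frame `scale, direction, mean, sd, t, df, p`.
#' @export
questionnaire_tests <- function(scores, definitions = scale_definitions(),
                                midpoint = 2.5) {
  rows <- lapply(seq_len(nrow(definitions)), function(d) {
    sc <- definitions$scale[d]
    r <- midpoint_ttest(scores[[sc]], midpoint, definitions$direction[d])
    cbind(data.frame(scale = sc, direction = definitions$direction[d]), r)
  })
  do.call(rbind, rows)
}

#' Simulate questionnaire scale scores
#'
#' Draws per-participant scale scores from normal distributions clipped to
#' the 1-5 rating range. Default means and SDs describe a well-tolerated,
#' immersive system: high usability, low sickness/oculomotor/disorientation
#' scores, mid-to-high immersion, presence, realism and involvement.
#'
#' @param scale_means,scale_sds named per-scale means (must lie in
#'   `[1, 5]`) and SDs (non-negative); defaults cover the eight scales of
#'   [scale_definitions()].
#' @param n number of participants (default 37).
#' @param seed integer seed.
#' @return A data.frame `participant_id` plus one column per scale.
#' @export
simulate_questionnaire <- function(
    scale_means = c(usability = 4.5, sickness = 1.16,
                    oculomotor_problems = 1.35, disorientation = 1.16,
                    immersion = 3.6, presence = 3.11, realism = 2.92,
                    involvement = 3.08),
    scale_sds = c(usability = 0.6, sickness = 0.4,
                  oculomotor_problems = 0.5, disorientation = 0.5,
                  immersion = 1.2, presence = 1.1, realism = 1.38,
                  involvement = 0.8),
    n = 37, seed = 1L) {
  if (any(scale_means < 1 | scale_means > 5))
    stop("'scale_means' must lie within the rating scale [1, 5]",
         call. = FALSE)
  if (any(scale_sds < 0))
    stop("'scale_sds' must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  out <- data.frame(participant_id = seq_len(n))
  for (s in names(scale_means))
    out[[s]] <- clip(rnorm(n, scale_means[[s]], scale_sds[[s]]), 1, 5)
  out
}

#' Simulate item-level questionnaire responses
#'
#' Integer 1-5 responses per item: each item is drawn around its scale's
#' mean with the scale's SD, rounded and clipped; item 17 (favourite
#' video) is a uniform choice among the videos.
#'
#' @inheritParams simulate_questionnaire
#' @param n_videos number of videos for item 17.
#' @param definitions scale definitions mapping items to scales.
#' @return A data.frame `participant_id, item_1 .. item_17`.
#' @export
simulate_questionnaire_items <- function(
    scale_means = eval(formals(simulate_questionnaire)$scale_means),
    scale_sds = eval(formals(simulate_questionnaire)$scale_sds),
    n = 37, n_videos = 3, seed = 1L,
    definitions = scale_definitions()) {
  if (any(scale_means < 1 | scale_means > 5))
    stop("'scale_means' must lie within the rating scale [1, 5]",
         call. = FALSE)
  set.seed(as.integer(seed))
  out <- data.frame(participant_id = seq_len(n))
  for (it in 1:17) out[[paste0("item_", it)]] <- NA_integer_
  for (d in seq_len(nrow(definitions))) {
    sc <- definitions$scale[d]
    for (it in parse_items(definitions$items[d]))
      out[[paste0("item_", it)]] <-
        as.integer(clip(round(rnorm(n, scale_means[[sc]], scale_sds[[sc]])),
                        1, 5))
  }
  out$item_17 <- sample.int(n_videos, n, replace = TRUE)
  out
}
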