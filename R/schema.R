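#' Feature schema for a student cohort
#'
#' A schema names the features of a cohort, assigns each one to one of four
#' blocks of student life — learning behaviour (`"learn"`), social interaction
#' (`"social"`), physical health (`"physical"`) and mental state (`"mental"`)
#' — and records the finite value range each raw feature lives on. The block
#' assignment drives the default PERMA prior (see [default_perma_prior()]) and
#' the latent loadings of the synthetic generator.
#'
#' @param feature_names character vector of unique feature identifiers.
#' @param block_of named character vector mapping every feature to one of
#'   `"learn"`, `"social"`, `"physical"`, `"mental"`. All four blocks must be
#'   non-empty.
#' @param value_range numeric matrix with one row per feature and columns
#'   `min`, `max` (finite, `min < max`). Defaults to `[0, 1]` for every
#'   feature.
#' @return An object of class `"perma_schema"`.
#' @export
#' @examples
#' sch <- perma_schema(
#'   c("study_hours", "friends", "sleep", "mood"),
#'   c(study_hours = "learn", friends = "social", sleep = "physical",
#'     mood = "mental"))
#' sch$d
perma_schema <- function(feature_names, block_of, value_range = NULL) {
  blocks <- c("learn", "social", "physical", "mental")
  if (!is.character(feature_names) || anyDuplicated(feature_names) ||
      length(feature_names) < 4L) {
    stopf("`feature_names` must be >= 4 unique feature identifiers")
  }
  if (is.null(names(block_of))) names(block_of) <- feature_names
  if (!setequal(names(block_of), feature_names)) {
    stopf("`block_of` must name exactly the schema features")
  }
  block_of <- block_of[feature_names]
  if (!all(block_of %in% blocks)) {
    stopf("blocks must be one of: %s", paste(blocks, collapse = ", "))
  }
  missing_blocks <- setdiff(blocks, unique(block_of))
  if (length(missing_blocks)) {
    stopf("every block must be non-empty; missing: %s",
          paste(missing_blocks, collapse = ", "))
  }
  d <- length(feature_names)
  if (is.null(value_range)) {
    value_range <- cbind(min = rep(0, d), max = rep(1, d))
  }
  value_range <- as.matrix(value_range)
  colnames(value_range) <- c("min", "max")
  rownames(value_range) <- feature_names
  if (nrow(value_range) != d || !all(is.finite(value_range)) ||
      any(value_range[, 1] >= value_range[, 2])) {
    stopf("`value_range` must be d x 2, finite, with min < max per feature")
  }
  structure(
    list(feature_names = feature_names, block_of = block_of,
         value_range = value_range, d = d),
    class = "perma_schema")
}

#' @export
print.perma_schema <- function(x, ...) {
  cat(sprintf("<perma_schema> %d features\n", x$d))
  print(table(factor(x$block_of,
                     levels = c("learn", "social", "physical", "mental"))))
  invisible(x)
}

# Names of the five PERMA dimensions, in canonical order.
#' PERMA dimension names
#'
#' The five dimensions of Seligman's PERMA framework, in the fixed order used
#' throughout the package: Positive emotions, Engagement, Relationships,
#' Meaning, Achievement.
#' @return `c("P", "E", "R", "M", "A")`
#' @export
perma_dims <- function() c("P", "E", "R", "M", "A")

# Block -> dominant PERMA dimension(s). Learning behaviour speaks to
# Engagement/Achievement, social interaction to Relationships, physical
# health to Positive emotions, mental state to Positive emotions/Meaning.
block_dominant_dims <- function() {
  list(learn = c("E", "A"), social = "R", physical = "P", mental = c("P", "M"))
}

#' Default 23-feature schema
#'
#' A ready-made schema mirroring the shape of work-life-balance style surveys:
#' 23 bounded features split across the four blocks (6 learning, 5 social,
#' 6 physical, 6 mental), all on the unit interval.
#'
#' @param d number of features; the default 23 matches the large survey
#'   preset. Must be at least 4; features are distributed round-robin over
#'   blocks beyond the named 23.
#' @return A [perma_schema()].
#' @export
default_schema <- function(d = 23L) {
  base <- c(
    study_hours = "learn", class_participation = "learn", task_completion = "learn",
    learning_motivation = "learn", skill_practice = "learn", course_load = "learn",
    social_time = "social", close_friends = "social", community_events = "social",
    family_contact = "social", peer_support = "social",
    sleep_hours = "physical", exercise_freq = "physical", diet_quality = "physical",
    daily_steps = "physical", health_checkups = "physical", bmi_norm = "physical",
    mood_score = "mental", optimism = "mental", calmness = "mental",
    self_esteem = "mental", life_purpose = "mental", gratitude = "mental")
  d <- as.integer(d)
  if (d < 4L) stopf("`d` must be >= 4")
  if (d <= length(base)) {
    blocks <- base[seq_len(d)]
    # keep all four blocks represented even for tiny d
    if (length(setdiff(c("learn", "social", "physical", "mental"),
                       unique(blocks)))) {
      blocks <- stats::setNames(
        rep(c("learn", "social", "physical", "mental"), length.out = d),
        paste0("f", seq_len(d)))
    }
  } else {
    extra <- stats::setNames(
      rep(c("learn", "social", "physical", "mental"), length.out = d - length(base)),
      paste0("extra_", seq_len(d - length(base))))
    blocks <- c(base, extra)
  }
  perma_schema(names(blocks), blocks)
}
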