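#' Build a 65-trial sentence-picture matching design
#'
#' Generates the trial list the synthetic study is built on: 15 active,
#' 15 passive, and 15 locative experimental trials plus 20 intransitive
#' fillers (10 declarative, 10 wh-question). Target side is balanced within
#' each structure type (an odd count splits 8/7, with the majority side
#' randomized). Per-trial disambiguation times — the noun onset for actives
#' and passives, the first-preposition onset for locatives — are drawn
#' uniformly from per-structure windows on the trial clock, which starts at
#' trial onset (300 ms fixation cross + 700 ms picture apprehension precede
#' the audio, so all disambiguation times exceed 1000 ms).
#'
#' @param seed integer seed; fully determines the design.
#' @param disamb_window_ms named list of `c(lo, hi)` disambiguation windows
#'   (ms from trial onset) per structure type, all starting above 1000 ms.
#' @param audio_tail_ms `c(lo, hi)` range of the audio remaining after the
#'   disambiguation point; audio duration = disambiguation + tail.
#'
#' @return a `data.frame` with one row per trial: `trial_id`, `structure`
#'   (`active`/`passive`/`locative`/`filler`), `filler_type` (`declarative`,
#'   `wh`, or `NA`), `target_side` (`left`/`right`), `disamb_ms`, `audio_ms`.
#' @export
#' @examples
#' d <- build_design(seed = 1)
#' table(d$structure)
build_design <- function(seed = 1L,
                         disamb_window_ms = list(
                           active = c(1600, 2400), passive = c(1600, 2400),
                           locative = c(1500, 2300), filler = c(1400, 2200)),
                         audio_tail_ms = c(800, 1500)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  counts <- c(active = 15L, passive = 15L, locative = 15L,
              `filler-declarative` = 10L, `filler-wh` = 10L)
  structure <- rep(c("active", "passive", "locative", "filler", "filler"),
                   times = counts)
  filler_type <- rep(c(NA, NA, NA, "declarative", "wh"), times = counts)

  side <- unlist(lapply(counts, function(n) {
    n_left <- n %/% 2L + sample(0:1, 1L) * (n %% 2L)
    sample(rep(c("left", "right"), c(n_left, n - n_left)))
  }), use.names = FALSE)

  key <- ifelse(structure == "filler", "filler", structure)
  win <- do.call(rbind, disamb_window_ms[key])
  disamb <- runif(length(structure), win[, 1], win[, 2])
  audio <- disamb + runif(length(structure), audio_tail_ms[1], audio_tail_ms[2])

  ord <- sample(length(structure))
  out <- data.frame(
    trial_id = sprintf("t%02d", seq_along(structure)),
    structure = structure[ord],
    filler_type = filler_type[ord],
    target_side = side[ord],
    disamb_ms = round(disamb[ord], 1),
    audio_ms = round(audio[ord], 1),
    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
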