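# Cohort metadata: a reference active-tracking summary table shipped as a
# plain-CSV fixture, plus a generator for synthetic cohorts with the same
# schema (duration classes 24/38/48 h and removal-note codes drawn with
# configurable probabilities).

#' Reference active-tracking cohort table
#'
#' Loads the packaged 21-shark active-tracking summary (ID, length, girth,
#' sex, track duration class, dates, logger model, tagging site, removal
#' note). Removal notes use the codes `tag_loss`, `track_loss`,
#' `logger_malfunction`, or empty.
#'
#' @return data.frame, one row per shark.
#' @export
cohort_table1 <- function() {
  path <- system.file("extdata", "cohort_table1.csv", package = "trackpatch",
                      mustWork = TRUE)
  ch <- read.csv(path, stringsAsFactors = FALSE)
  ch$note[is.na(ch$note)] <- ""
  ch
}

#' Generate a synthetic cohort metadata table
#'
#' @param n_sharks number of sharks (>= 1).
#' @param seed RNG seed; a fixed seed reproduces the table exactly.
#' @param p_note probabilities of removal-note codes
#'   `c(tag_loss, track_loss, logger_malfunction)`; the remainder get no
#'   note.
#' @return data.frame with the same schema as [cohort_table1()].
#' @export
make_cohort <- function(n_sharks, seed = 1,
                        p_note = c(tag_loss = 0.05, track_loss = 0.05,
                                   logger_malfunction = 0.1)) {
  stopifnot(n_sharks >= 1, sum(p_note) < 1)
  set.seed(seed)
  sites <- c("BFC", "IR", "BR", "CG")
  dur <- sample(c(24, 38, 48), n_sharks, replace = TRUE,
                prob = c(0.45, 0.05, 0.5))
  d0 <- as.Date("2017-06-01") + sort(sample(0:140, n_sharks, replace = TRUE))
  notes <- sample(c(names(p_note), ""), n_sharks, replace = TRUE,
                  prob = c(p_note, 1 - sum(p_note)))
  data.frame(
    shark_id = sprintf("Shark %02d", seq_len(n_sharks)),
    length_cm = round(pmin(pmax(rnorm(n_sharks, 73.2, 6.25), 55), 95), 1),
    girth_cm = round(pmin(pmax(rnorm(n_sharks, 32, 4), 20), 42), 1),
    sex = sample(c("F", "M"), n_sharks, replace = TRUE, prob = c(0.6, 0.4)),
    duration_h = dur,
    dates = format(d0, "%d %b %Y"),
    adl_model = sample(c("Cefas G6a+", "TechnoSmArt Axy-Depth"), n_sharks,
                       replace = TRUE),
    site = sample(sites, n_sharks, replace = TRUE),
    note = notes,
    stringsAsFactors = FALSE
  )
}
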