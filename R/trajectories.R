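# Belief trajectories: one participant x referent run of the feedback task.
#
# A run consists of a pre-feedback probability report, 20 binary feedback
# events (1 = chosen/positive, 0 = not chosen/negative) and a report after
# each event: 21 reports in total. Reports are always stored on the
# canonical "probability of being in the top half" scale; runs elicited
# under the bottom-half framing are flipped (q -> 1 - q) at ingest.

N_TRIALS <- 20L

#' Construct a belief trajectory
#'
#' @param participant_id Opaque participant identifier.
#' @param referent `"self"` or `"other"`: whose popularity is judged.
#' @param framing `"top_half"` or `"bottom_half"`: how the probability
#'   question was framed when the data were collected. Reports passed here
#'   must already be on the canonical top-half scale (see
#'   [read_trajectories()] for raw-frame ingest).
#' @param feedback Integer vector of 20 binary feedback events.
#' @param reports Numeric vector of 21 probability reports in `[0, 1]`;
#'   `reports[1]` is the pre-feedback report.
#' @param feedback_order `"positive_first"` or `"negative_first"`, the
#'   pre-randomised sequence the participant received.
#' @return An object of class `belief_trajectory`.
#' @seealso [read_trajectories()], [simulate_trajectory()]
#' @export
belief_trajectory <- function(participant_id, referent, framing, feedback,
                              reports, feedback_order = NA_character_) {
  referent <- match.arg(referent, c("self", "other"))
  framing <- match.arg(framing, c("top_half", "bottom_half"))
  if (!is.na(feedback_order)) {
    feedback_order <- match.arg(feedback_order, c("positive_first", "negative_first"))
  }
  .check(length(feedback) == N_TRIALS, sprintf("feedback must have length %d", N_TRIALS))
  .check(length(reports) == N_TRIALS + 1L, sprintf("reports must have length %d", N_TRIALS + 1L))
  .check(.is_binary(feedback), "feedback events must all be 0 or 1")
  .check(.is_prob(reports), "all reports must lie in [0, 1]")
  structure(
    list(
      participant_id = as.character(participant_id),
      referent = referent,
      framing = framing,
      feedback = as.integer(feedback),
      reports = as.numeric(reports),
      feedback_order = feedback_order
    ),
    class = "belief_trajectory"
  )
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf(
    "<belief_trajectory> participant %s, %s-referent, %s framing\n  feedback: %s\n  reports:  q0 = %.2f ... q%d = %.2f\n",
    x$participant_id, x$referent, x$framing,
    paste(x$feedback, collapse = ""),
    x$reports[1], as.integer(N_TRIALS), x$reports[N_TRIALS + 1L]
  ))
  invisible(x)
}

#' Read belief trajectories from a long-format CSV
#'
#' The file dialect is one row per trial per run with columns
#' `participant_id, referent, framing, feedback_order, trial, feedback,
#' report`. `trial` runs 0..20; `feedback` is empty (NA) on trial 0.
#' Reports recorded under the `bottom_half` framing are stored in the file
#' on the scale the participant answered and are flipped to the canonical
#' top-half scale on ingest.
#'
#' @param path CSV file path.
#' @return A list of [belief_trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "referent", "framing", "feedback_order",
            "trial", "feedback", "report")
  .check(all(need %in% names(df)), paste("missing columns:",
                                         paste(setdiff(need, names(df)), collapse = ", ")))
  key <- paste(df$participant_id, df$referent, sep = "_")
  trs <- lapply(split(df, key), function(run) {
    run <- run[order(run$trial), ]
    .check(identical(run$trial, 0:N_TRIALS),
           sprintf("run %s/%s: trial column must be 0..%d",
                   run$participant_id[1], run$referent[1], N_TRIALS))
    reports <- run$report
    if (run$framing[1] == "bottom_half") reports <- 1 - reports
    belief_trajectory(
      participant_id = run$participant_id[1],
      referent = run$referent[1],
      framing = run$framing[1],
      feedback = run$feedback[-1],
      reports = reports,
      feedback_order = run$feedback_order[1]
    )
  })
  trs[order(names(trs))]
}

#' Write belief trajectories to a long-format CSV
#'
#' Inverse of [read_trajectories()]: canonical top-half reports of
#' `bottom_half`-framed runs are flipped back to the raw frame before
#' writing, so a read/write cycle round-trips.
#'
#' @param trajectories List of [belief_trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    reports <- tr$reports
    if (tr$framing == "bottom_half") reports <- 1 - reports
    data.frame(
      participant_id = tr$participant_id,
      referent = tr$referent,
      framing = tr$framing,
      feedback_order = tr$feedback_order,
      trial = 0:N_TRIALS,
      feedback = c(NA_integer_, tr$feedback),
      report = reports
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
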