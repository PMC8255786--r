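#' Assemble a trial table
#'
#' One row per binary choice trial: the session it belongs to, the stimuli
#' offered left and right, the offered magnitudes (mL, strictly positive)
#' and the side chosen. Extra columns (e.g. `agent_id`, `flavor`) are
#' preserved as metadata.
#'
#' @param df A data.frame with columns `session_id`, `trial`, `stim_left`,
#'   `stim_right`, `mag_left`, `mag_right`, `choice`.
#' @return The validated data.frame with class `"choice_trials"`, ordered by
#'   session and trial index.
#' @export
choice_trials <- function(df) {
  need <- c("session_id", "trial", "stim_left", "stim_right",
            "mag_left", "mag_right", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial data missing required column: ", paste(miss, collapse = ", "))
  }
  bad <- which(!(df$mag_left > 0) | !(df$mag_right > 0))
  if (length(bad)) {
    stop("non-positive reward magnitude at row ", bad[1])
  }
  if (!all(df$choice %in% c("left", "right"))) {
    stop("choice must be 'left' or 'right'")
  }
  df <- df[order(df$session_id, df$trial), , drop = FALSE]
  rownames(df) <- NULL
  for (sid in unique(df$session_id)) {
    idx <- df$trial[df$session_id == sid]
    if (!identical(as.integer(idx), seq_along(idx) - 1L)) {
      stop("trial indices of session '", sid, "' not contiguous from 0")
    }
  }
  class(df) <- c("choice_trials", "data.frame")
  df
}

#' Read trial-level choice records
#'
#' Reads a comma-delimited UTF-8 file with one row per trial. Required
#' header columns: `session_id, trial, stim_left, stim_right, mag_left,
#' mag_right, choice`; unknown columns are kept. Rows are grouped by session
#' and ordered by the 0-based trial index.
#'
#' @param path Path to the CSV file.
#' @return A [choice_trials()] table.
#' @seealso [write_trials()], [split_sessions()]
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  choice_trials(df)
}

#' Write trial-level choice records to CSV
#'
#' @param trials A [choice_trials()] table.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Split a trial table into per-session tables
#'
#' @param trials A [choice_trials()] table.
#' @return Named list of `choice_trials`, one per session, in order of first
#'   appearance.
#' @export
split_sessions <- function(trials) {
  out <- split(as.data.frame(trials), factor(trials$session_id,
                                             levels = unique(trials$session_id)))
  lapply(out, function(d) {
    rownames(d) <- NULL
    class(d) <- c("choice_trials", "data.frame")
    d
  })
}

# Trial-level design matrix pieces shared by every choice model: left-right
# differences of log magnitude, nutrient concentrations, texture parameters
# and offered energy. y = 1 codes a leftward choice.
choice_design <- function(trials, stimuli) {
  sl <- match(trials$stim_left, stimuli$id)
  sr <- match(trials$stim_right, stimuli$id)
  if (anyNA(sl) || anyNA(sr)) {
    bad <- unique(c(trials$stim_left[is.na(sl)], trials$stim_right[is.na(sr)]))
    stop("trials reference stimuli absent from the stimulus table: ",
         paste(bad, collapse = ", "))
  }
  data.frame(
    session_id = trials$session_id,
    y = as.integer(trials$choice == "left"),
    dlogmag = log(trials$mag_left) - log(trials$mag_right),
    dfat = stimuli$fat[sl] - stimuli$fat[sr],
    dsugar = stimuli$sugar[sl] - stimuli$sugar[sr],
    dfatsugar = stimuli$fat[sl] * stimuli$sugar[sl] -
      stimuli$fat[sr] * stimuli$sugar[sr],
    dvisc = stimuli$viscosity[sl] - stimuli$viscosity[sr],
    dcsf = stimuli$csf[sl] - stimuli$csf[sr],
    denergy = trials$mag_left * stimuli$energy_density[sl] -
      trials$mag_right * stimuli$energy_density[sr],
    dfat_level = as.numeric(stimuli$fat_level[sl] == "high") -
      as.numeric(stimuli$fat_level[sr] == "high"),
    dsugar_level = as.numeric(stimuli$sugar_level[sl] == "high") -
      as.numeric(stimuli$sugar_level[sr] == "high"),
    stringsAsFactors = FALSE
  )
}

#' Choice-history regressors
#'
#' For each trial, an exponentially decaying tally of recent choices of the
#' higher-fat (higher-sugar) option, signed by which side currently carries
#' more fat (sugar). Positive weights on these regressors produce
#' positive-feedback choice dynamics: having recently chosen fat makes the
#' current fat option more attractive.
#'
#' @param trials A [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @param window Number of past trials considered.
#' @param decay Exponential decay per trial back, in (0, 1].
#' @return Data frame with columns `hist_fat` and `hist_sugar`, one row per
#'   trial (zero for the first trials of each session).
#' @export
history_regressors <- function(trials, stimuli, window = 5, decay = 0.7) {
  des <- choice_design(trials, stimuli)
  hf <- hs <- numeric(nrow(des))
  w <- decay^(seq_len(window) - 1)
  for (sid in unique(des$session_id)) {
    rows <- which(des$session_id == sid)
    # +1 when the chosen option was the fattier of the pair, -1 when leaner
    chose_fat <- sign(ifelse(des$y[rows] == 1, des$dfat[rows], -des$dfat[rows]))
    chose_sug <- sign(ifelse(des$y[rows] == 1, des$dsugar[rows],
                             -des$dsugar[rows]))
    for (t in seq_along(rows)) {
      back <- t - seq_len(min(window, t - 1))
      if (!length(back)) next
      hf[rows[t]] <- sign(des$dfat[rows[t]]) *
        sum(w[seq_along(back)] * chose_fat[back])
      hs[rows[t]] <- sign(des$dsugar[rows[t]]) *
        sum(w[seq_along(back)] * chose_sug[back])
    }
  }
  data.frame(hist_fat = hf, hist_sugar = hs)
}
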