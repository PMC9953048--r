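#' Select analyzable frames for a condition
#'
#' Drops excluded frames (confounding behaviors such as licking the pipet
#' or self-scratching) and, for tastant conditions, keeps only frames
#' captured while the animal tasted the solution or in the 5 s following a
#' tasting event (both window ends inclusive), so that the measured
#' expression reflects the taste before it fades.
#'
#' @param frames Frame-level parameter table (see [measure_frames()]).
#' @param condition Condition label to select.
#' @param tasting_events Named list: per animal, numeric vector of tasting
#'   event times in seconds (on the `phase_time_s` axis). Required for
#'   tastant conditions.
#' @param tastants Character vector of condition labels treated as
#'   tastants.
#' @param window_s Length of the post-tasting window in seconds.
#' @return Subset of `frames`.
#' @export
select_frames <- function(frames, condition, tasting_events = NULL,
                          tastants = c("water", "sucrose", "quinine",
                                       "mentholatum"),
                          window_s = 5) {
  stopifnot(is.data.frame(frames))
  out <- frames[frames$condition == condition & !frames$excluded, ,
                drop = FALSE]
  if (condition %in% tastants) {
    if (is.null(tasting_events) || length(tasting_events) == 0L) {
      stop("tastant condition '", condition,
           "' requires tasting events", call. = FALSE)
    }
    keep <- vapply(seq_len(nrow(out)), function(i) {
      ev <- tasting_events[[as.character(out$animal_id[i])]]
      if (is.null(ev)) {
        stop("no tasting events for animal ", out$animal_id[i],
             call. = FALSE)
      }
      t <- out$phase_time_s[i]
      any(t >= ev & t <= ev + window_s)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Average frames into per-individual per-condition units
#'
#' All frames from one individual under one condition are averaged into a
#' single unit — the atom of every downstream analysis — so that animals
#' contributing many frames do not dominate group statistics.
#'
#' @param frames Frame-level parameter table with non-excluded rows.
#' @return Data frame with one row per (animal_id, condition):
#'   `animal_id`, `condition`, `experiment_id` (first observed),
#'   `n_frames`, and the seven parameter means. Groups with zero frames
#'   are absent, never zero-filled.
#' @export
unit_average <- function(frames) {
  stopifnot(is.data.frame(frames))
  if ("excluded" %in% names(frames)) {
    frames <- frames[!frames$excluded, , drop = FALSE]
  }
  if (!nrow(frames)) stop("no frames to average")
  pars <- intersect(facial_parameters(), names(frames))
  if (!length(pars)) stop("no parameter columns present")
  key <- interaction(frames$animal_id, frames$condition, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(frames)), key)
  rows <- lapply(idx, function(i) {
    sub <- frames[i, , drop = FALSE]
    means <- vapply(pars, function(p) mean(sub[[p]]), numeric(1))
    data.frame(animal_id = sub$animal_id[1],
               condition = sub$condition[1],
               experiment_id = if ("experiment_id" %in% names(sub))
                 sub$experiment_id[1] else NA_character_,
               n_frames = nrow(sub),
               as.list(means))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportional change from baseline
#'
#' For each animal and stimulus, computes per parameter
#' (value at stimulus - value at baseline) / value at baseline, the
#' individual-normalized effect measure underlying response profiles.
#' An exactly zero baseline value makes the fraction undefined for that
#' parameter and is returned as `NA` rather than infinity.
#'
#' @param units Unit table from [unit_average()].
#' @param baseline Label of the baseline condition.
#' @return Data frame, one row per (animal_id, non-baseline condition),
#'   parameter columns holding fractions.
#' @export
proportional_change <- function(units, baseline = "baseline") {
  stopifnot(is.data.frame(units))
  pars <- intersect(facial_parameters(), names(units))
  base <- units[units$condition == baseline, , drop = FALSE]
  stim <- units[units$condition != baseline, , drop = FALSE]
  if (!nrow(stim)) stop("no stimulus units present")
  missing_base <- setdiff(unique(stim$animal_id), base$animal_id)
  if (length(missing_base)) {
    stop("missing baseline unit for animal(s): ",
         paste(missing_base, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(base$animal_id)) {
    stop("multiple baseline units for animal(s): ",
         paste(unique(base$animal_id[duplicated(base$animal_id)]),
               collapse = ", "), call. = FALSE)
  }
  b <- base[match(stim$animal_id, base$animal_id), pars, drop = FALSE]
  s <- stim[, pars, drop = FALSE]
  frac <- (s - b) / b
  frac[b == 0] <- NA_real_
  out <- cbind(stim[, intersect(c("animal_id", "condition", "experiment_id"),
                                names(stim)), drop = FALSE], frac)
  rownames(out) <- NULL
  out
}

#' Temporal binning for the formalin test
#'
#' The formalin assay produces a biphasic nocifensive response; its
#' time course is summarized by averaging the whole pre-injection baseline
#' phase into a single reference bin and splitting the post-injection
#' phase into six 5-min intervals (half-open, `[start, end)` minutes).
#' Two derived summaries follow the conventional phase definitions:
#' `early` = the first 5 min post injection, `late` = the 20-30 min
#' interval.
#'
#' @param frames Frame-level parameter table for one injection
#'   experiment; `phase_time_s` is seconds since phase onset and
#'   `condition` distinguishes the baseline phase (label in
#'   `baseline_condition`) from the post-injection phase.
#' @param baseline_condition Label of the baseline phase.
#' @param baseline_min,post_min Phase durations in minutes.
#' @param bin_min Post-injection bin width in minutes.
#' @return List with `bins` (one row per animal x bin: `animal_id`,
#'   `bin_label` = "baseline"/"1".."6", `start_min`, `end_min`,
#'   `n_frames`, parameter means) and `phases` (per animal `early` and
#'   `late` rows). Frames outside both phase windows are dropped with a
#'   warning.
#' @export
formalin_bins <- function(frames, baseline_condition = "baseline",
                          baseline_min = 30, post_min = 30, bin_min = 5) {
  stopifnot(is.data.frame(frames))
  pars <- intersect(facial_parameters(), names(frames))
  if ("excluded" %in% names(frames)) {
    frames <- frames[!frames$excluded, , drop = FALSE]
  }
  min_t <- frames$phase_time_s / 60
  is_base <- frames$condition == baseline_condition
  in_base <- is_base & min_t >= 0 & min_t < baseline_min
  in_post <- !is_base & min_t >= 0 & min_t < post_min
  n_out <- sum(!(in_base | in_post))
  if (n_out > 0) {
    warning(n_out, " frame(s) outside the baseline and post-injection ",
            "windows were dropped")
  }
  n_bins <- post_min / bin_min
  mk <- function(sub, label, start, end) {
    if (!nrow(sub)) return(NULL)
    means <- vapply(pars, function(p) mean(sub[[p]]), numeric(1))
    data.frame(animal_id = sub$animal_id[1], bin_label = label,
               start_min = start, end_min = end, n_frames = nrow(sub),
               as.list(means))
  }
  rows <- list()
  for (an in unique(frames$animal_id)) {
    sel_an <- frames$animal_id == an
    rows[[length(rows) + 1L]] <-
      mk(frames[sel_an & in_base, , drop = FALSE], "baseline",
         0, baseline_min)
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * bin_min
      hi <- b * bin_min
      sel <- sel_an & in_post & min_t >= lo & min_t < hi
      rows[[length(rows) + 1L]] <-
        mk(frames[sel, , drop = FALSE], as.character(b), lo, hi)
    }
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  phases <- list()
  for (an in unique(frames$animal_id)) {
    sel_an <- frames$animal_id == an
    early <- mk(frames[sel_an & in_post & min_t >= 0 & min_t < 5, ,
                       drop = FALSE], "early", 0, 5)
    late <- mk(frames[sel_an & in_post & min_t >= 20 & min_t < 30, ,
                      drop = FALSE], "late", 20, 30)
    phases <- c(phases, list(early), list(late))
  }
  phases <- do.call(rbind, phases)
  rownames(phases) <- NULL
  list(bins = bins, phases = phases)
}

#' Pool unit tables across experiments
#'
#' Animals from different experiments that received the same stimulation
#' are grouped for analysis; pooling is pure concatenation (experiment
#' provenance retained, no re-averaging across animals).
#'
#' @param ... Unit tables from [unit_average()], or a single list of them.
#' @param allow_duplicates Permit the same (animal_id, condition) pair in
#'   more than one table.
#' @return Concatenated unit table.
#' @export
pool_conditions <- function(..., allow_duplicates = FALSE) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  out <- do.call(rbind, tabs)
  key <- paste(out$animal_id, out$condition, sep = "\r")
  if (!allow_duplicates && anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (animal, condition) across experiments: ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
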