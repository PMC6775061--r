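## Goal-oriented adaptive sampling on the activation descriptors.
##
## Campaigns run short trajectories in epochs; new epochs are respawned
## from stored frames ranked by a mix of a goal score (progress along
## the activation descriptors) and an exploration bonus (inverse visit
## count of the frame's descriptor-space microstate). The dynamics law
## is never modified - only the initial conditions of new trajectories.

#' Specify the activation goal
#'
#' Linear per-dimension scaling between an inactive anchor and an active
#' cap, clamped to [0, 1] and averaged over the two descriptors. The
#' defaults anchor at the inactive state (lock 2 A, RMSD 0) and cap at
#' the active-state extremes (lock 12 A, the largest TM3-TM6 separation;
#' RMSD at the fully rotated TM7 position).
#'
#' @param lock_anchor,lock_cap Ionic-lock distance anchors (A).
#' @param rmsd_anchor,rmsd_cap Y7.53 RMSD anchors (A).
#' @return A `goal_spec` list.
#' @export
goal_spec <- function(lock_anchor = 2, lock_cap = 12,
                      rmsd_anchor = 0, rmsd_cap = 4) {
  stopifnot(lock_cap > lock_anchor, rmsd_cap > rmsd_anchor)
  structure(list(lock_anchor = lock_anchor, lock_cap = lock_cap,
                 rmsd_anchor = rmsd_anchor, rmsd_cap = rmsd_cap),
            class = "goal_spec")
}

#' Goal score of descriptor values
#'
#' Monotone nondecreasing in each descriptor up to its cap; 0 at (or
#' below) the inactive anchors, 1 at (or beyond) both active caps.
#'
#' @param lock_distance,y753_rmsd Descriptor vectors.
#' @param spec A `goal_spec`.
#' @return Scores in [0, 1].
#' @export
goal_score <- function(lock_distance, y753_rmsd, spec = goal_spec()) {
  sl <- (lock_distance - spec$lock_anchor) /
    (spec$lock_cap - spec$lock_anchor)
  sr <- (y753_rmsd - spec$rmsd_anchor) /
    (spec$rmsd_cap - spec$rmsd_anchor)
  (pmin(pmax(sl, 0), 1) + pmin(pmax(sr, 0), 1)) / 2
}

## Coarse descriptor-space microstate of frames (fixed 0.5 A grid),
## used only for the exploration bonus.
frame_microstate <- function(lock, rmsd, cell = 0.5) {
  paste(floor(lock / cell), floor(rmsd / cell))
}

#' Select restart frames for the next epoch
#'
#' Frames are ranked by `mix * goal + (1 - mix) / sqrt(1 + visits)`,
#' where `visits` counts stored frames in the candidate frame's
#' descriptor-space microstate. Ties are broken deterministically by
#' lowest frame id. Requesting more frames than stored returns all
#' frames.
#'
#' @param frames Tibble with `lock_distance`, `y753_rmsd` (all stored
#'   frames, in storage order; frame id = row number).
#' @param n Number of restarts.
#' @param mix Goal weight in [0, 1] (0 = pure exploration).
#' @param spec A `goal_spec`.
#' @return Integer frame ids (row indices into `frames`).
#' @export
select_restarts <- function(frames, n, mix = 0.5, spec = goal_spec()) {
  stopifnot(mix >= 0, mix <= 1, nrow(frames) >= 1)
  g <- goal_score(frames$lock_distance, frames$y753_rmsd, spec)
  ms <- frame_microstate(frames$lock_distance, frames$y753_rmsd)
  visits <- table(ms)
  expl <- 1 / sqrt(1 + as.numeric(visits[ms]))
  score <- mix * g + (1 - mix) * expl
  if (n >= nrow(frames)) return(seq_len(nrow(frames)))
  order(-score, seq_along(score))[seq_len(n)]
}

#' Run an adaptive sampling campaign
#'
#' Epochs of short Langevin trajectories on a landscape. The first epoch
#' starts every trajectory from the inactive configuration; later epochs
#' respawn from frames chosen by [select_restarts()] (`respawn =
#' "goal"`) or uniformly at random from stored frames (`respawn =
#' "uniform"`). Per-step dynamics are identical in both modes. The
#' campaign records the first epoch and simulated-frame effort at which
#' any trajectory enters the target basin region (default M2, within
#' `target_radius` of its centre in width-scaled distance).
#'
#' @param model A `landscape_model`.
#' @param epochs Number of epochs.
#' @param traj_per_epoch Trajectories per epoch.
#' @param steps Frames per trajectory.
#' @param seed Master seed; per-epoch seeds are derived from it.
#' @param mix Goal/exploration weight for `respawn = "goal"`.
#' @param respawn `"goal"` or `"uniform"`.
#' @param spec A `goal_spec`.
#' @param dt Langevin time step.
#' @param start Start point of epoch 1 (inactive configuration).
#' @param target Basin label whose first entry is recorded.
#' @param target_radius Entry radius in width-scaled units.
#' @return An `epoch_state`: list with `frames` (all stored frames with
#'   `epoch`), `log` tibble (epoch, n_frames, best_goal, coverage),
#'   `first_passage` (list: epoch, effort_frames; NA if never reached),
#'   `respawn`, `seed`.
#' @export
run_campaign <- function(model, epochs, traj_per_epoch, steps, seed,
                         mix = 0.5, respawn = c("goal", "uniform"),
                         spec = goal_spec(), dt = 0.025,
                         start = c(2.0, 0.5), target = "M2",
                         target_radius = 2) {
  respawn <- match.arg(respawn)
  b <- model$basins
  ti <- match(target, b$state)
  stopifnot(!is.na(ti))
  frames <- NULL
  log <- NULL
  fp <- list(epoch = NA_integer_, effort_frames = NA_real_)
  for (ep in seq_len(epochs)) {
    if (ep == 1) {
      starts <- matrix(rep(start, traj_per_epoch), ncol = 2, byrow = TRUE)
    } else {
      if (respawn == "goal") {
        ids <- select_restarts(frames, traj_per_epoch, mix, spec)
      } else {
        set.seed(as.integer(seed) + 7919L * ep)
        ids <- sample.int(nrow(frames), traj_per_epoch, replace = TRUE)
      }
      ids <- rep(ids, length.out = traj_per_epoch)
      starts <- as.matrix(frames[ids, c("lock_distance", "y753_rmsd")])
    }
    tr <- sample_langevin(model, traj_per_epoch, steps, dt = dt,
                          seed = as.integer(seed) + 104729L * ep,
                          start = starts)
    tr$epoch <- ep
    ## first entry into the target region
    if (is.na(fp$epoch)) {
      dtar <- sqrt(((tr$lock_distance - b$lock[ti]) / b$sigma_l[ti])^2 +
                     ((tr$y753_rmsd - b$rmsd[ti]) / b$sigma_r[ti])^2)
      hit <- which(dtar < target_radius)
      if (length(hit) > 0) {
        f1 <- min(tr$frame[hit])
        fp <- list(epoch = ep,
                   effort_frames = (ep - 1) * traj_per_epoch * steps +
                     f1 * traj_per_epoch)
      }
    }
    frames <- dplyr::bind_rows(frames, tr)
    log <- dplyr::bind_rows(log, tibble::tibble(
      epoch = ep, n_frames = nrow(frames),
      best_goal = max(goal_score(frames$lock_distance,
                                 frames$y753_rmsd, spec)),
      coverage = length(unique(frame_microstate(frames$lock_distance,
                                                frames$y753_rmsd)))))
  }
  structure(list(frames = frames, log = log, first_passage = fp,
                 respawn = respawn, seed = seed),
            class = "epoch_state")
}

#' @export
print.epoch_state <- function(x, ...) {
  cat("Adaptive campaign (", x$respawn, " respawning): ",
      max(x$log$epoch), " epochs, ", nrow(x$frames), " frames\n", sep = "")
  if (!is.na(x$first_passage$epoch))
    cat("  target reached in epoch", x$first_passage$epoch,
        "after", x$first_passage$effort_frames, "simulated frames\n")
  else cat("  target never reached\n")
  invisible(x)
}
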