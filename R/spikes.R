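#' Detect motoneuron spikes in a voltage trace
#'
#' A spike is registered at each upward crossing of the threshold and
#' timestamped at the subsequent local voltage maximum. After an accepted
#' spike, further crossings are ignored for a short lockout interval.
#'
#' @param sim An `mn_sim` object from [simulate_mn()], or a numeric voltage
#'   trace (then `time`, `period` and `rest` must be supplied).
#' @param threshold Spike threshold (mV); the model cell's threshold is
#'   -40 mV.
#' @param lockout Detector dead time after a spike (ms).
#' @param time,period,rest Required when `sim` is a bare numeric trace.
#' @return An object of class `spike_train`: data frame with columns
#'   `time` (ms, spike peak), `phase` (% stroke cycle in `[0, 100)`) and
#'   `amplitude` (mV above rest), with attributes `period` and `rest`.
#' @export
detect_spikes <- function(sim, threshold = -40, lockout = 1,
                          time = NULL, period = NULL, rest = NULL) {
  if (inherits(sim, "mn_sim")) {
    U <- sim$U
    time <- sim$time
    period <- if (is.null(period)) sim$period else period
    rest <- sim$rest
  } else {
    U <- sim
    if (is.null(time) || is.null(period) || is.null(rest))
      stop("bare traces need time, period and rest")
  }
  if (!all(is.finite(U))) stop("non-finite voltage trace")
  n <- length(U)
  cross <- which(U[-1] >= threshold & U[-n] < threshold)
  t_sp <- numeric(0)
  a_sp <- numeric(0)
  last <- -Inf
  dt <- time[2] - time[1]
  for (k in cross) {
    if (time[k] - last < lockout) next
    i <- k + 1
    while (i < n && U[i + 1] >= U[i]) i <- i + 1
    t_sp <- c(t_sp, time[i])
    a_sp <- c(a_sp, U[i] - rest)
    last <- time[k]
  }
  structure(data.frame(time = t_sp,
                       phase = (t_sp %% period) / period * 100,
                       amplitude = a_sp),
            period = period, rest = rest, class = c("spike_train", "data.frame"))
}

#' Circular mean and SD of stroke-cycle phases
#'
#' Phases live on a circle of circumference 100 (% stroke cycle); these
#' helpers are invariant to adding whole periods and robust to wrap-around
#' at 0/100%.
#'
#' @param phase Phases in % stroke cycle.
#' @return `phase_mean`: mean phase in `[0, 100)`. `phase_sd`: circular
#'   standard deviation in % cycle (equals the linear SD for tight
#'   distributions).
#' @export
phase_mean <- function(phase) {
  ang <- 2 * pi * phase / 100
  m <- (Arg(mean(exp(1i * ang))) / (2 * pi) * 100) %% 100
  if (m > 100 - 1e-9) 0 else m
}

#' @rdname phase_mean
#' @export
phase_sd <- function(phase) {
  ang <- 2 * pi * phase / 100
  R <- Mod(mean(exp(1i * ang)))
  sqrt(pmax(-2 * log(R), 0)) / (2 * pi) * 100 + 0 # +0 normalises IEEE -0
}

#' Classify p:q mode locking of a spike train
#'
#' Searches for the smallest pattern length `q <= q_max` such that the
#' per-cycle spike-count sequence over the analysis window repeats with
#' period `q` and each within-pattern spike slot keeps a fixed phase
#' (circular SD below `tol_phase`). A window with no spikes is quiescence;
#' a window with spikes but no admissible `q` is irregular firing.
#'
#' @param train A `spike_train` from [detect_spikes()].
#' @param period Stroke period (ms); defaults to the train's.
#' @param t_start Start of the analysis window (ms); transient cycles must
#'   already lie before it.
#' @param n_cycles Number of analysed cycles; the window must hold at least
#'   `3 * q` cycles for a pattern of length `q` to be accepted.
#' @param tol_phase Maximum per-slot phase SD (% cycle) for locking.
#' @param q_max Largest pattern length searched.
#' @return An object of class `locking_report`: list with `mode`
#'   (`"quiescence"`, `"locked"` or `"irregular"`), `p`, `q`, a `slots`
#'   data frame (per-slot mean phase, phase SD, count), the overall
#'   `mean_phase`, `phase_sd` and the firing frequency `F_MN` (Hz).
#' @export
classify_locking <- function(train, period = attr(train, "period"),
                             t_start = 0, n_cycles = 100,
                             tol_phase = 1, q_max = 8) {
  if (n_cycles < 3) stop("analysis window must span at least 3 cycles")
  t_end <- t_start + n_cycles * period
  sel <- train$time >= t_start & train$time < t_end
  times <- train$time[sel]
  phases <- train$phase[sel]
  F_MN <- length(times) / (n_cycles * period) * 1000

  base <- list(slots = NULL, F_MN = F_MN,
               mean_phase = if (length(phases)) phase_mean(phases) else NA_real_,
               phase_sd = if (length(phases)) phase_sd(phases) else NA_real_,
               n_spikes = length(times), n_cycles = n_cycles)
  if (length(times) == 0)
    return(structure(c(list(mode = "quiescence", p = 0L, q = 1L), base),
                     class = "locking_report"))

  cyc <- floor((times - t_start) / period)
  counts <- tabulate(cyc + 1, nbins = n_cycles)
  within <- stats::ave(seq_along(times), cyc, FUN = seq_along)

  for (q in seq_len(min(q_max, floor(n_cycles / 3)))) {
    ok <- TRUE
    for (r in seq_len(q)) {
      idx <- seq(r, n_cycles, by = q)
      if (length(unique(counts[idx])) > 1) { ok <- FALSE; break }
    }
    if (!ok) next
    slot_id <- paste((cyc %% q) + 1, within, sep = ".")
    sds <- tapply(phases, slot_id, phase_sd)
    if (any(sds >= tol_phase)) next
    slots <- data.frame(
      slot = names(sds),
      mean_phase = as.numeric(tapply(phases, slot_id, phase_mean)),
      sd_phase = as.numeric(sds),
      n = as.integer(table(slot_id)[names(sds)]))
    p <- sum(counts[seq_len(q)])
    base$slots <- slots[order(slots$slot), , drop = FALSE]
    return(structure(c(list(mode = "locked", p = as.integer(p),
                            q = as.integer(q)), base),
                     class = "locking_report"))
  }
  structure(c(list(mode = "irregular", p = NA_integer_, q = NA_integer_), base),
            class = "locking_report")
}

#' @export
print.locking_report <- function(x, ...) {
  lab <- switch(x$mode,
                quiescence = "quiescence",
                irregular = sprintf("irregular (%d spikes / %d cycles)",
                                    x$n_spikes, x$n_cycles),
                locked = sprintf("%d:%d locked", x$p, x$q))
  cat(sprintf("Locking: %s; F_MN = %.2f Hz", lab, x$F_MN))
  if (!is.na(x$mean_phase))
    cat(sprintf("; mean phase = %.2f%% cycle (SD %.3f)", x$mean_phase, x$phase_sd))
  cat("\n")
  invisible(x)
}
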