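#' Detected synaptic event train
#'
#' Events detected upstream from a voltage-clamp recording (event
#' detection itself is out of scope; this consumes the detector's event
#' table).
#'
#' @param cell_id Cell identifier.
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param event_times Event times in s, strictly increasing within
#'   `[0, duration]`.
#' @param amplitudes Event amplitudes in pA.
#' @param charges Per-event charges in pC (>= 0).
#' @param duration Recording duration in s (> 0).
#' @param holding_voltage Holding voltage in mV.
#' @return An `event_train` object.
#' @export
event_train <- function(cell_id, polarity = c("excitatory", "inhibitory"),
                        event_times, amplitudes, charges, duration,
                        holding_voltage = NA_real_) {
  polarity <- match.arg(polarity)
  n <- length(event_times)
  if (length(amplitudes) != n || length(charges) != n)
    stop("event_times, amplitudes and charges must have equal length")
  if (duration <= 0) stop("duration must be > 0")
  if (n > 0) {
    if (any(diff(event_times) <= 0)) stop("event times must be strictly increasing")
    if (min(event_times) < 0 || max(event_times) > duration)
      stop("event times must lie in [0, duration]")
    if (any(charges < 0)) stop("charges must be >= 0")
  }
  structure(list(cell_id = cell_id, polarity = polarity,
                 event_times = as.numeric(event_times),
                 amplitudes = as.numeric(amplitudes),
                 charges = as.numeric(charges),
                 duration = as.numeric(duration),
                 holding_voltage = holding_voltage),
            class = "event_train")
}

#' Read event tables into event trains
#'
#' Column dictionary: `cell_id`, `polarity`, `time_s`, `amplitude_pA`,
#' `charge_pC`, `duration_s`, and optionally `holding_mV`. One
#' [event_train] is built per (cell_id, polarity).
#'
#' @param file CSV path.
#' @return Named list of [event_train] objects
#'   (`<cell_id>.<polarity>`).
#' @export
read_event_csv <- function(file) {
  tab <- utils::read.csv(file)
  need <- c("cell_id", "polarity", "time_s", "amplitude_pA", "charge_pC",
            "duration_s")
  if (!all(need %in% names(tab)))
    stop("event table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(tab$cell_id, tab$polarity, sep = "."))) {
    sub <- tab[paste(tab$cell_id, tab$polarity, sep = ".") == key, ]
    sub <- sub[order(sub$time_s), ]
    out[[key]] <- event_train(sub$cell_id[1], sub$polarity[1], sub$time_s,
                              sub$amplitude_pA, sub$charge_pC,
                              duration = sub$duration_s[1],
                              holding_voltage =
                                if ("holding_mV" %in% names(sub))
                                  sub$holding_mV[1] else NA_real_)
  }
  out
}

#' Per-cell event-train summary
#'
#' Frequency is the exact event count over the recording duration (no
#' binning); current per second is the average per-event charge times the
#' frequency. An empty train has frequency 0 and NA means, with
#' `empty = TRUE` flagging that the means are undefined.
#'
#' @param t An [event_train].
#' @return One-row data.frame: `cell_id`, `polarity`, `n_events`,
#'   `mean_amplitude` (pA), `frequency` (Hz), `mean_charge` (pC),
#'   `current_per_second` (pC/s), `empty`.
#' @export
train_summary <- function(t) {
  stopifnot(inherits(t, "event_train"))
  n <- length(t$event_times)
  freq <- n / t$duration
  if (n == 0L)
    return(data.frame(cell_id = t$cell_id, polarity = t$polarity,
                      n_events = 0L, mean_amplitude = NA_real_,
                      frequency = 0, mean_charge = NA_real_,
                      current_per_second = NA_real_, empty = TRUE))
  mc <- mean(t$charges)
  data.frame(cell_id = t$cell_id, polarity = t$polarity, n_events = n,
             mean_amplitude = mean(t$amplitudes), frequency = freq,
             mean_charge = mc, current_per_second = mc * freq,
             empty = FALSE)
}

#' Excitation/inhibition ratio for one cell
#'
#' E/I ratio = (excitatory current/second) / (inhibitory current/second),
#' computed from the two trains of the same cell.
#'
#' @param exc,inh [event_train] objects (excitatory / inhibitory) from
#'   the same cell.
#' @return Dimensionless ratio.
#' @export
ei_ratio <- function(exc, inh) {
  stopifnot(inherits(exc, "event_train"), inherits(inh, "event_train"))
  if (!identical(exc$cell_id, inh$cell_id))
    stop("E/I ratio requires trains from the same cell")
  se <- train_summary(exc); si <- train_summary(inh)
  if (si$empty || si$current_per_second == 0)
    stop("inhibitory current per second is zero; ratio undefined")
  if (se$empty) return(0)
  se$current_per_second / si$current_per_second
}

#' Paired-pulse ratio
#'
#' PPR = peak2 / peak1 after subtracting any residual current from the
#' first response still present at the second pulse
#' (`(peak2_raw - residual_at_p2) / peak1`).
#'
#' @param peak1 First-pulse peak amplitude in pA (non-zero).
#' @param peak2_raw Raw second-pulse peak in pA.
#' @param residual_at_p2 Residual current at the second pulse in pA.
#' @param inter_stimulus_interval Interval in ms (> 0; default 50).
#' @return Dimensionless ratio.
#' @export
ppr <- function(peak1, peak2_raw, residual_at_p2 = 0,
                inter_stimulus_interval = 50) {
  if (inter_stimulus_interval <= 0)
    stop("inter_stimulus_interval must be > 0")
  if (peak1 == 0) stop("peak1 must be non-zero")
  (peak2_raw - residual_at_p2) / peak1
}

#' Quality-control partition of recorded cells
#'
#' A cell is excluded when access resistance exceeds 25 MOhm, the
#' absolute holding current exceeds 200 pA (at -60 mV; the absolute value
#' is used because the sign depends on the holding potential), or — where
#' a series-resistance change was measured (evoked recordings) — that
#' change exceeds 20%. All rules are strict inequalities; boundary values
#' are kept. Reasons enumerate every violated rule.
#'
#' @param cells data.frame with columns `cell_id`, `Ra` (MOhm), `Ihold`
#'   (pA) and optionally `Rs_change` (percent; NA where not applicable).
#' @param ra_max,ihold_max,rs_change_max Exclusion bounds.
#' @return `cells` with added `excluded` (logical) and `reason`
#'   (comma-separated violated rules, `""` if kept).
#' @export
apply_qc <- function(cells, ra_max = 25, ihold_max = 200, rs_change_max = 20) {
  need <- c("cell_id", "Ra", "Ihold")
  if (!all(need %in% names(cells)))
    stop("QC table needs columns: ", paste(need, collapse = ", "))
  if (!"Rs_change" %in% names(cells)) cells$Rs_change <- NA_real_
  reasons <- vapply(seq_len(nrow(cells)), function(i) {
    r <- character(0)
    if (cells$Ra[i] > ra_max) r <- c(r, "access-resistance")
    if (abs(cells$Ihold[i]) > ihold_max) r <- c(r, "holding-current")
    if (!is.na(cells$Rs_change[i]) && cells$Rs_change[i] > rs_change_max)
      r <- c(r, "series-resistance-change")
    paste(r, collapse = ",")
  }, character(1))
  cells$excluded <- nzchar(reasons)
  cells$reason <- reasons
  cells
}

#' Integrate an event waveform to a charge
#'
#' Helper for event tables lacking charges: trapezoidal integral of a
#' baseline-subtracted current waveform. Current in pA integrated over
#' time in s gives charge directly in pC (1 pA x 1 s = 1 pC).
#'
#' @param time_s Sample times in s (increasing).
#' @param current_pA Current samples in pA.
#' @param baseline Baseline current in pA (subtracted before
#'   integration); default the mean of the first 5 samples.
#' @return Absolute charge in pC.
#' @export
event_charge <- function(time_s, current_pA,
                         baseline = mean(utils::head(current_pA, 5))) {
  if (length(time_s) != length(current_pA) || length(time_s) < 2)
    stop("need matching time and current vectors of length >= 2")
  y <- current_pA - baseline
  abs(sum(diff(time_s) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}
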