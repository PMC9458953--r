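#' Operating schedule for a temperature-staged run
#'
#' The reactor is run at a fixed hydraulic residence time (HRT) through an
#' ordered sequence of temperature stages. Within each stage the floating
#' biofilm is physically disrupted every `disruption_interval` residence
#' times (fragments settle onto the harvest screen) and the accumulated
#' biofilm is removed for drying and elemental analysis every
#' `harvest_interval` residence times. Samples are drawn from the four
#' in-reactor ports and the effluent at a fixed interval.
#'
#' @param hrt Hydraulic residence time (h).
#' @param stage_temps_c Stage temperatures (degC), applied in order. The
#'   default steps from 30 to 10 degC in 5 degC decrements.
#' @param stage_duration_rt Duration of each stage in residence times
#'   (recycled to the length of `stage_temps_c`).
#' @param disruption_interval Residence times between biofilm disruptions.
#' @param harvest_interval Residence times between biofilm harvests; must
#'   be an integer multiple of `disruption_interval`.
#' @param sample_interval Sampling interval (h).
#'
#' @return A `reactor_schedule` list; its `$stages` element is a tibble
#'   with `stage`, `temp_c`, `start_h`, `end_h`.
#' @examples
#' reactor_schedule()
#' @export
reactor_schedule <- function(hrt = 48,
                             stage_temps_c = c(30, 25, 20, 15, 10),
                             stage_duration_rt = 6,
                             disruption_interval = 3,
                             harvest_interval = 6,
                             sample_interval = 24) {
  if (hrt <= 0) abort("`hrt` must be positive.", class = "lfcr_domain_error")
  if (length(stage_temps_c) == 0) {
    abort("Schedule needs at least one temperature stage.", class = "lfcr_config_error")
  }
  dur <- rep_len(stage_duration_rt, length(stage_temps_c))
  if (any(dur <= 0)) abort("Stage durations must be positive.", class = "lfcr_domain_error")
  if (disruption_interval <= 0 || harvest_interval <= 0 || sample_interval <= 0) {
    abort("Intervals must be positive.", class = "lfcr_domain_error")
  }
  ratio <- harvest_interval / disruption_interval
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`harvest_interval` must be an integer multiple of `disruption_interval`.",
      class = "lfcr_config_error"
    )
  }
  end_h <- cumsum(dur * hrt)
  stages <- tibble(
    stage = seq_along(stage_temps_c),
    temp_c = as.numeric(stage_temps_c),
    start_h = c(0, head(end_h, -1)),
    end_h = end_h
  )
  structure(
    list(
      hrt = hrt, stages = stages,
      disruption_interval = disruption_interval,
      harvest_interval = harvest_interval,
      sample_interval = sample_interval
    ),
    class = "reactor_schedule"
  )
}

#' @export
print.reactor_schedule <- function(x, ...) {
  cat(sprintf(
    "<reactor_schedule> HRT %g h, %d stages (%s degC), disrupt/%g RT, harvest/%g RT\n",
    x$hrt, nrow(x$stages), paste(x$stages$temp_c, collapse = ", "),
    x$disruption_interval, x$harvest_interval
  ))
  invisible(x)
}

# Event times (h) over the whole schedule.
schedule_events <- function(schedule) {
  total <- max(schedule$stages$end_h)
  dis <- schedule$disruption_interval * schedule$hrt
  har <- schedule$harvest_interval * schedule$hrt
  list(
    disruption = seq(dis, total, by = dis),
    harvest = seq(har, total, by = har),
    sample = seq(schedule$sample_interval, total, by = schedule$sample_interval),
    total_h = total
  )
}

# Stage temperature at time t (h); stage intervals are (start, end].
stage_temp_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$stages$start_h, left.open = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(schedule$stages)] <- nrow(schedule$stages)
  schedule$stages$temp_c[idx]
}
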