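#' Adaptive acquisition-interval controller
#'
#' Implements the positive feedback loop between tracking quality and data
#' acquisition: when tracking quality drops below `q_low` the time step
#' interval is reduced by `factor` (more frequent imaging rescues the
#' linker); when quality exceeds `q_high` the interval is increased by
#' `factor` (sparser imaging spares the cells light exposure). Decisions
#' use the mean quality over a sliding window, are suppressed for
#' `cooldown` steps after a change, and the window is cleared on change -
#' together with the hysteresis gap `q_low < q_high` this prevents
#' oscillation.
#'
#' @param interval start interval in seconds.
#' @param interval_min,interval_max interval bounds in seconds.
#' @param q_low,q_high quality thresholds, `0 <= q_low < q_high <= 1`.
#' @param factor multiplicative adjustment factor (> 1).
#' @param window number of recent quality values averaged per decision.
#' @param cooldown steps after a change during which no further change is
#'   allowed (choose `>= window` so decisions never straddle a change).
#' @return a `pt_controller` state list.
#' @export
adaptive_controller <- function(interval = 30, interval_min = 30,
                                interval_max = 900, q_low = 0.80,
                                q_high = 0.95, factor = 2, window = 5L,
                                cooldown = 5L) {
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
    stop_config("need 0 <= q_low < q_high <= 1")
  if (factor <= 1) stop_config("factor must be > 1")
  if (interval < interval_min || interval > interval_max)
    stop_config("interval must start within [interval_min, interval_max]")
  structure(list(current_interval = interval,
                 interval_min = interval_min, interval_max = interval_max,
                 q_low = q_low, q_high = q_high, factor = factor,
                 window = as.integer(window),
                 cooldown = as.integer(cooldown),
                 quality_window = numeric(0),
                 steps_since_change = Inf),
            class = "pt_controller")
}

#' Fraction of objects carried forward by the linker
#'
#' The tracking-quality signal: the fraction of frame-A objects that
#' receive a link into frame B under [link_frames()] at threshold `D`.
#' It is 1 when every object is carried forward, degrades exactly when
#' tracking degrades, and is computable online during acquisition. An
#' empty frame A scores 1 (nothing was lost).
#'
#' @param A,B `pt_objects` of two consecutive acquisitions.
#' @param D linking threshold in px.
#' @return fraction in `[0, 1]`.
#' @export
link_quality <- function(A, B, D) {
  if (nrow(A) == 0) return(1)
  nrow(link_frames(A, B, D)) / nrow(A)
}

#' One controller update
#'
#' Appends the new quality value to the window and, if allowed (cooldown
#' elapsed), applies the rule: windowed mean below `q_low` halves the
#' interval (divides by `factor`, clamped at `interval_min`); above
#' `q_high` multiplies by `factor` (clamped at `interval_max`); otherwise
#' the interval is held. The window is cleared whenever the interval
#' changes.
#'
#' @param state a `pt_controller`.
#' @param q new quality observation in `[0, 1]`.
#' @return the updated `pt_controller`.
#' @export
adapt_interval <- function(state, q) {
  stopifnot(inherits(state, "pt_controller"))
  state$quality_window <- tail(c(state$quality_window, q), state$window)
  state$steps_since_change <- state$steps_since_change + 1
  if (state$steps_since_change < state$cooldown) return(state)
  m <- mean(state$quality_window)
  new_iv <- state$current_interval
  if (m < state$q_low) {
    new_iv <- max(state$current_interval / state$factor, state$interval_min)
  } else if (m > state$q_high) {
    new_iv <- min(state$current_interval * state$factor, state$interval_max)
  }
  if (new_iv != state$current_interval) {
    state$current_interval <- new_iv
    state$quality_window <- numeric(0)
    state$steps_since_change <- 0
  }
  state
}

#' Replay a stored acquisition under adaptive interval control
#'
#' Emulates a microscope whose time step interval is under closed-loop
#' control, using a pre-acquired base-interval sequence as the virtual
#' specimen: at each acquisition the stored frame nearest to the current
#' time is served. After each new acquisition the link quality between the
#' two most recent frames is measured at the interval-appropriate
#' threshold `D` and fed to [adapt_interval()]. Requested intervals below
#' the stored base interval are clamped (with a warning in the log).
#'
#' @param seq a [image_sequence()] at the base interval.
#' @param controller a [adaptive_controller()].
#' @param config a [run_config()]; supplies the segmentation backend, area
#'   bounds and the `D` rule.
#' @return a `pt_adaptation` list: `log` (data frame `step, time_s,
#'   interval_s, quality`), `final_interval`, and `tracks` (trajectories
#'   assembled over the acquired frames, unfiltered).
#' @export
run_adaptive <- function(seq, controller = adaptive_controller(),
                         config = run_config()) {
  stopifnot(inherits(controller, "pt_controller"))
  rule <- threshold_rule(config$D_anchors)
  base <- seq$interval
  nf <- length(seq)
  # lazily segmented objects per stored frame
  bg <- NULL
  tau <- config$tau
  if (config$segmentation_backend == "bgsub") {
    bg <- reconstruct_background(seq)
    if (is.null(tau)) tau <- estimate_tau(seq, bg)
  }
  cache <- vector("list", nf)
  get_objects <- function(i) {
    if (is.null(cache[[i]])) {
      fr <- seq$frames[[i]]
      mask <- if (config$segmentation_backend == "bgsub") {
        subtract_and_threshold(fr, bg, tau)
      } else {
        evolve_contours(fr, detect_edges(fr))
      }
      cache[[i]] <<- mask_to_objects(mask, config$area_bounds,
                                     frame_index = seq$frame_index[i])
    }
    cache[[i]]
  }
  t_now <- 0
  i_prev <- 1L
  acquired <- i_prev
  link_store <- list()
  log_rows <- list()
  step <- 0L
  repeat {
    iv <- controller$current_interval
    if (iv < base) {
      warning("requested interval ", iv, " s below stored base ", base,
              " s; clamped", call. = FALSE)
      iv <- base
      controller$current_interval <- base
    }
    t_next <- t_now + iv
    i_next <- as.integer(round(t_next / base)) + 1L
    if (i_next > nf) break
    if (i_next == i_prev) i_next <- i_prev + 1L   # always advance
    step <- step + 1L
    D <- threshold_for_interval(rule, iv)
    A <- get_objects(i_prev)
    B <- get_objects(i_next)
    lk <- link_frames(A, B, D)
    q <- if (nrow(A) == 0) 1 else nrow(lk) / nrow(A)
    controller <- adapt_interval(controller, q)
    log_rows[[step]] <- data.frame(step = step, time_s = t_next,
                                   interval_s = iv, quality = q)
    link_store[[length(acquired)]] <- lk
    acquired <- c(acquired, i_next)
    t_now <- t_next
    i_prev <- i_next
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), time_s = numeric(),
               interval_s = numeric(), quality = numeric())
  acq_seq <- image_sequence(seq$frames[acquired],
                            pixel_size = seq$pixel_size,
                            interval = base,   # irregular; times via index
                            origin_interval = seq$origin_interval,
                            origin_duration = seq$origin_duration,
                            frame_index = seq$frame_index[acquired],
                            bit_depth = seq$bit_depth)
  tracks <- build_trajectories(lapply(acquired, get_objects), link_store,
                               acq_seq)
  structure(list(log = log,
                 final_interval = controller$current_interval,
                 controller = controller, tracks = tracks),
            class = "pt_adaptation")
}

#' @export
print.pt_adaptation <- function(x, ...) {
  cat(sprintf("Adaptive acquisition: %d steps, final interval %g s\n",
              nrow(x$log), x$final_interval))
  iv <- rle(x$log$interval_s)
  cat("  interval sequence:",
      paste(sprintf("%gs x%d", iv$values, iv$lengths), collapse = ", "),
      "\n")
  invisible(x)
}
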