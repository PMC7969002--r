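#' Write E* traces (and optional ground truth) to tabular text
#'
#' Long format, tab-separated: columns `trace_id`, `frame` (0-based),
#' `estar`; ground-truth paths go to a companion file with a `state` column.
#' Frame time and any extra metadata are stored in a DCF sidecar
#' (`<path>.meta`).
#'
#' @param traces List of `fret_trace` objects.
#' @param path Output file.
#' @param paths Optional list of `true_path`/`state_path` objects written to
#'   `<path>.states`.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, paths = NULL, meta = list()) {
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id,
               frame = seq_along(tr$estar) - 1L,
               estar = sprintf("%.17g", tr$estar),  # round-trip exact
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(frame_time = traces[[1]]$frame_time,
                 n_traces = length(traces)), meta)
  write.dcf(data.frame(lapply(side, as.character), check.names = FALSE),
            paste0(path, ".meta"))
  if (!is.null(paths)) {
    ptab <- do.call(rbind, lapply(paths, function(p) {
      data.frame(trace_id = p$trace_id %||% NA_character_,
                 frame = seq_along(p$states) - 1L,
                 state = p$states, stringsAsFactors = FALSE)
    }))
    write.table(ptab, paste0(path, ".states"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read traces from tabular text
#'
#' Accepts the package's long formats: E* traces (`trace_id`, `frame`,
#' `estar`) or intensity traces (`trace_id`, `frame`, `I_DD`, `I_DA`,
#' `I_AA`). Frames must be contiguous from 0 within each trace; gaps are
#' rejected with the offending trace named. Frame time comes from the DCF
#' sidecar (`<path>.meta`) or the `frame_time` argument.
#'
#' @param path Input file.
#' @param format `"estar"` or `"intensity"`.
#' @param frame_time Frame time in seconds; overrides the sidecar.
#' @return List of `fret_trace` or `intensity_trace` objects (empty list,
#'   with a warning, for an empty file).
#' @export
read_traces <- function(path, format = c("estar", "intensity"),
                        frame_time = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(frame_time)) {
    side <- paste0(path, ".meta")
    if (!file.exists(side))
      stop("frame_time not given and sidecar ", side, " not found")
    frame_time <- as.numeric(read.dcf(side)[1, "frame_time"])
  }
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty trace file: ", path)
    return(list())
  }
  need <- if (format == "estar") c("trace_id", "frame", "estar")
          else c("trace_id", "frame", "I_DD", "I_DA", "I_AA")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("malformed file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(tab[need]))
  if (length(bad) > 0L)
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  out <- lapply(split(tab, tab$trace_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (!identical(as.integer(d$frame), seq_len(nrow(d)) - 1L))
      stop("frame numbering gap in trace ", d$trace_id[1],
           " (near line ", which(tab$trace_id == d$trace_id[1])[1] + 1L, ")")
    if (format == "estar")
      fret_trace(d$trace_id[1], d$estar, frame_time)
    else
      intensity_trace(d$trace_id[1], d$I_DD, d$I_DA, d$I_AA, frame_time)
  })
  unname(out[unique(tab$trace_id)])
}

#' Run the reference clamp-dynamics simulation studies end to end
#'
#' Two canonical studies of the three-state clamp model driven by the 20-ms
#' reference rates ([rnap_clamp_rates()]), state means (0.20, 0.30, 0.42)
#' and stationary initial conditions:
#' \describe{
#'   \item{`short`}{200 traces x 470 frames at 20 ms with per-frame noise
#'     SD 0.070.}
#'   \item{`binned`}{fine 20-ms paths block-averaged by 10 to 200-ms frames,
#'     noise SD 0.068, 200 traces x 600 frames (emulating slow
#'     acquisition).}
#' }
#' Each dataset is fitted with a pooled 3-state VB-HMM, decoded, and
#' summarised: occupancies, recovered rates, mean dwells, static/dynamic
#' census, long-dwell fractions.
#'
#' @param which `"short"` or `"binned"`.
#' @param seed Root seed for simulation and fitting.
#' @param n_restarts Restarts for the HMM fit.
#' @return List with `dataset`, `model`, `paths`, `occupancy_pct`,
#'   `rates` (s^-1), `dwell_means` (s), `census`, `long_dwell_pct`
#'   (per state, uncensored dwells > 5 s), and a one-row `summary`
#'   data.frame of the headline quantities.
#' @export
run_reference_simulation <- function(which = c("short", "binned"), seed = 1,
                                 n_restarts = 2) {
  which <- match.arg(which)
  emis <- if (which == "short") emission_spec(c(0.20, 0.30, 0.42), 0.070)
          else emission_spec(c(0.20, 0.30, 0.42), 0.068)
  cfg <- if (which == "short")
    sim_config(rnap_clamp_rates(), emis, frame_time = 0.02,
               n_traces = 200, n_frames = 470, bin_factor = 1L, seed = seed)
  else
    sim_config(rnap_clamp_rates(), emis, frame_time = 0.2,
               n_traces = 200, n_frames = 600, bin_factor = 10L, seed = seed)
  ds <- simulate_dataset(cfg)
  model <- fit_hmm(ds$traces, K = 3, n_restarts = n_restarts,
                   seed = trace_seed(seed, 101L))
  paths <- decode_paths(model, ds$traces)
  occ <- occupancy(paths, K = 3)
  k <- rates_from_model(model)
  dwells <- do.call(rbind, lapply(paths, extract_dwells))
  long_pct <- vapply(0:2, function(s) {
    d <- dwells[dwells$state == s & !dwells$censored_start &
                  !dwells$censored_end, , drop = FALSE]
    if (nrow(d) == 0L) return(NA_real_)
    100 * mean(d$seconds > 5.0)
  }, numeric(1))
  census <- dynamic_census(paths)
  dwell_means <- vapply(1:3, function(i) mean_dwell(k, i), numeric(1))
  summary <- data.frame(
    which = which, seed = seed,
    occ_open_pct = 100 * occ[1], occ_pc_pct = 100 * occ[2],
    occ_closed_pct = 100 * occ[3],
    k_O_PC = k[1, 2], k_O_C = k[1, 3], k_PC_O = k[2, 1], k_PC_C = k[2, 3],
    k_C_O = k[3, 1], k_C_PC = k[3, 2],
    t_O = dwell_means[1], t_PC = dwell_means[2], t_C = dwell_means[3],
    long_dwell_open_pct = long_pct[1], long_dwell_pc_pct = long_pct[2],
    long_dwell_closed_pct = long_pct[3],
    n_static = census$n_static, n_dynamic = census$n_dynamic,
    row.names = NULL)
  list(dataset = ds, model = model, paths = paths,
       occupancy_pct = 100 * occ, rates = k, dwell_means = dwell_means,
       census = census, long_dwell_pct = long_pct, summary = summary)
}

#' Generate annotated intensity-trace fixtures
#'
#' Deterministic synthetic intensity traces for exercising the trace
#' selection and screening rules, each with ground-truth annotations.
#'
#' @param kind One of `"bleach"` (single acceptor step), `"multi_bleach"`
#'   (two donor steps), `"early_bleach"` (acceptor step before frame 50),
#'   `"blink"` (donor dark interval with recovery), `"static"` (no
#'   transitions), `"dynamic"` (two-state switching, anti-correlated DD/DA),
#'   `"two_state"` (E* traces from a well-separated two-state model).
#' @param seed Seed.
#' @param n_frames Frames per trace.
#' @param n_traces Number of traces (kind `two_state` and `dynamic`).
#' @param noise_sd Intensity noise SD in camera units.
#' @return List with `traces` (intensity traces, or `fret_trace`s for
#'   `two_state`) and `truth` (annotations: step frames, blink span, true
#'   states/levels).
#' @export
make_fixtures <- function(kind = c("bleach", "multi_bleach", "early_bleach",
                                   "blink", "static", "dynamic", "two_state"),
                          seed = 1, n_frames = 470L, n_traces = 10L,
                          noise_sd = 20) {
  kind <- match.arg(kind)
  set.seed(trace_seed(seed, 0L))
  base <- list(DD = 700, DA = 300, AA = 500)
  mk <- function(id, dd, da, aa)
    intensity_trace(id, dd + rnorm(length(dd), 0, noise_sd),
                    da + rnorm(length(da), 0, noise_sd),
                    aa + rnorm(length(aa), 0, noise_sd), 0.02)
  flat <- function(level) rep(level, n_frames)
  switch(kind,
    bleach = {
      step <- 400L
      aa <- c(rep(base$AA, step), rep(0, n_frames - step))
      list(traces = list(mk("bleach1", flat(base$DD), flat(base$DA), aa)),
           truth = list(acceptor_step = step))
    },
    multi_bleach = {
      s1 <- 150L; s2 <- 350L
      dd <- c(rep(base$DD, s1), rep(base$DD * 0.4, s2 - s1),
              rep(0, n_frames - s2))
      list(traces = list(mk("multi1", dd, dd * base$DA / base$DD,
                            flat(base$AA))),
           truth = list(donor_steps = c(s1, s2)))
    },
    early_bleach = {
      step <- 30L
      aa <- c(rep(base$AA, step), rep(0, n_frames - step))
      list(traces = list(mk("early1", flat(base$DD), flat(base$DA), aa)),
           truth = list(acceptor_step = step))
    },
    blink = {
      dark <- 200:240
      dd <- flat(base$DD); da <- flat(base$DA)
      dd[dark] <- 0; da[dark] <- 0
      list(traces = list(mk("blink1", dd, da, flat(base$AA))),
           truth = list(blink_span = range(dark) - 1L))
    },
    static = {
      list(traces = list(mk("static1", flat(base$DD), flat(base$DA),
                            flat(base$AA))),
           truth = list(transitions = 0L))
    },
    dynamic = {
      traces <- vector("list", n_traces)
      states <- vector("list", n_traces)
      for (i in seq_len(n_traces)) {
        z <- sim_path_core(matrix(c(0.97, 0.03, 0.05, 0.95), 2, 2, byrow = TRUE),
                           c(0.5, 0.5), runif(n_frames))
        e_level <- c(0.25, 0.55)[z + 1L]
        total <- base$DD + base$DA
        traces[[i]] <- mk(sprintf("dyn%02d", i), total * (1 - e_level),
                          total * e_level, flat(base$AA))
        states[[i]] <- z
      }
      list(traces = traces, truth = list(states = states))
    },
    two_state = {
      cfg <- sim_config(
        rate_spec(matrix(c(0, 2, 3, 0), 2, 2, byrow = TRUE)),
        emission_spec(c(0.2, 0.5), 0.05),
        frame_time = 0.02, n_traces = n_traces, n_frames = n_frames,
        seed = trace_seed(seed, 1L))
      ds <- simulate_dataset(cfg)
      list(traces = ds$traces, truth = list(K = 2L, paths = ds$paths))
    })
}
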