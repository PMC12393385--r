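#' Run the full permeation-analysis pipeline
#'
#' Orchestrates the stages ingest/generate -> detect -> segment ->
#' summarize -> aggregate -> waiting-time fits -> pathway classification,
#' logging each stage, and returns the collected artifacts. Three input
#' modes are supported: a [synthetic_spec()] (a run is generated from
#' `seed`), an existing [perm_bundle()], or a counts table (counts-only
#' mode, e.g. [table1_counts()], in which only the bookkeeping stages run).
#'
#' @param x a `synthetic_spec`, `perm_bundle`, or counts tibble with
#'   columns `segment`, `tb_k`, `bt_k`, `tb_cl`, `bt_cl`.
#' @param seed seed for synthetic generation.
#' @param ve_mv membrane voltage, mV; required for trajectory modes.
#' @param dt_ns segment length, ns; defaults to the run duration or (with
#'   `segment_ns`) the window length.
#' @param segment_ns optional analysis-window length for breaking long
#'   runs into independent segments, ns.
#' @param fit_waiting fit waiting-time models when enough events are
#'   available (default TRUE).
#' @param classify classify entry pathways (default TRUE; trajectory modes
#'   only).
#' @return a list of class `perm_report` with elements `events`,
#'   `summaries`, `aggregate`, `fits` (list), `pathways`, `table`
#'   (rendered), and `log` (tibble of stage, n, seconds).
#' @export
run_pipeline <- function(x, seed = 1L, ve_mv = NULL, dt_ns = NULL,
                         segment_ns = NULL, fit_waiting = TRUE,
                         classify = TRUE) {
  log <- list()
  tick <- function(stage, n, t0) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, n = n,
      seconds = as.numeric(Sys.time()) - t0)
  }
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline aborted at stage '%s': %s", stage,
                    conditionMessage(e)))
    })
  }

  counts_mode <- is.data.frame(x) &&
    all(c("tb_k", "bt_k", "tb_cl", "bt_cl") %in% names(x))
  events <- NULL; bundle <- NULL; pathways <- NULL; fits <- list()

  if (counts_mode) {
    t0 <- as.numeric(Sys.time())
    summaries <- stage_try("summarize",
                           summarize_events(x, dt_ns = dt_ns, ve_mv = ve_mv))
    tick("summarize", nrow(summaries), t0)
  } else {
    if (inherits(x, "synthetic_spec")) {
      t0 <- as.numeric(Sys.time())
      run <- stage_try("generate", generate_run(x, seed = seed))
      bundle <- run$bundle
      tick("generate", nrow(bundle$traces), t0)
    } else if (inherits(x, "perm_bundle")) {
      bundle <- x
    } else {
      abort("`x` must be a synthetic_spec, perm_bundle, or counts table.")
    }
    ve_mv <- ve_mv %||% bundle$metadata$voltage_mV
    t0 <- as.numeric(Sys.time())
    events <- stage_try("detect", detect_crossings(bundle))
    tick("detect", nrow(events), t0)
    if (!is.null(segment_ns)) {
      events <- assign_segments(events, segment_ns)
      dt_ns <- dt_ns %||% segment_ns
    }
    dt_ns <- dt_ns %||% bundle$metadata$duration_ns
    t0 <- as.numeric(Sys.time())
    summaries <- stage_try("conductance",
                           summarize_events(events, dt_ns = dt_ns,
                                            ve_mv = ve_mv))
    tick("conductance", nrow(summaries), t0)
    if (classify) {
      t0 <- as.numeric(Sys.time())
      pathways <- stage_try("pathways", classify_pathways(events, bundle))
      events <- pathways$events
      tick("pathways", nrow(events), t0)
    }
  }

  agg <- if (nrow(summaries) >= 2) aggregate_summaries(summaries) else NULL

  if (fit_waiting && !counts_mode) {
    t0 <- as.numeric(Sys.time())
    for (dirn in c("TB", "BT")) {
      w <- waiting_times(events, dirn)
      if (length(w) >= 3) {
        fits[[paste0(dirn, "_poisson")]] <- fit_poisson_quantile(w)
      }
      if (length(w) >= 10) {
        fits[[paste0(dirn, "_double_poisson")]] <-
          suppressWarnings(fit_double_poisson(w))
      }
    }
    durs <- event_durations(events)
    if (length(durs) >= 5) fits$durations <- fit_durations(durs)
    tick("fits", length(fits), t0)
  }

  structure(
    list(events = events, summaries = summaries, aggregate = agg,
         fits = fits, pathways = pathways,
         table = render_table1(summaries),
         log = dplyr::bind_rows(log), seed = seed),
    class = "perm_report"
  )
}

#' Render a per-segment event table with an average row
#'
#' Formats segment summaries in the standard layout: one row per segment
#' with the four event-count columns, net events and conductance, plus an
#' average row as `mean +/- standard error`.
#'
#' @param summaries a `run_summary` tibble (possibly empty).
#' @return a tibble of character columns `Index`, `TBK+`, `BTK+`, `TBCl-`,
#'   `BTCl-`, `Net Events`, `Conductance [pS]`.
#' @export
render_table1 <- function(summaries) {
  hdr <- c("Index", "TBK+", "BTK+", "TBCl-", "BTCl-", "Net Events",
           "Conductance [pS]")
  if (nrow(summaries) == 0) {
    out <- tibble::as_tibble(setNames(
      as.list(rep(list(character(0)), 7)), hdr))
    return(out)
  }
  rows <- tibble::tibble(
    `Index` = as.character(summaries$segment),
    `TBK+` = as.character(summaries$tb_k),
    `BTK+` = as.character(summaries$bt_k),
    `TBCl-` = as.character(summaries$tb_cl),
    `BTCl-` = as.character(summaries$bt_cl),
    `Net Events` = as.character(summaries$net_events),
    `Conductance [pS]` = sprintf("%.0f", summaries$conductance_pS)
  )
  pm <- function(v) {
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    sprintf("%.0f ± %.0f", mean(v), se)
  }
  avg <- tibble::tibble(
    `Index` = "Average",
    `TBK+` = pm(summaries$tb_k), `BTK+` = pm(summaries$bt_k),
    `TBCl-` = pm(summaries$tb_cl), `BTCl-` = pm(summaries$bt_cl),
    `Net Events` = pm(summaries$net_events),
    `Conductance [pS]` = pm(summaries$conductance_pS)
  )
  dplyr::bind_rows(rows, avg)
}

#' @export
print.perm_report <- function(x, ...) {
  cat("<perm_report>\n")
  print(x$table, n = Inf)
  if (length(x$fits)) {
    cat("\nFits:\n")
    for (nm in names(x$fits)) {
      cat(" ", nm, ": ", sep = "")
      print(x$fits[[nm]])
    }
  }
  invisible(x)
}
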