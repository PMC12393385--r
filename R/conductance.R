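#' Per-segment event counts, current and conductance
#'
#' Tallies complete crossings per segment into the standard bookkeeping
#' columns (TB/BT per species), computes the net charge translocation
#' `tb_k + bt_cl - bt_k - tb_cl`, the mean current
#' `I = e * net / dt` and the single-channel conductance `G = |I| / |Ve|`.
#' Conductances are reported as magnitudes: inward cation flux (TB at
#' negative voltage) gives positive G.
#'
#' @param events a `perm_events` tibble (see [detect_crossings()]), or a
#'   counts table with columns `segment`, `tb_k`, `bt_k`, `tb_cl`, `bt_cl`
#'   (counts-only mode, e.g. [table1_counts()]).
#' @param dt_ns segment length, ns; taken from a `dt_ns` column if present.
#' @param ve_mv membrane voltage, mV; taken from a `ve_mv` column if
#'   present. Conductance is undefined at zero voltage.
#' @return a tibble of class `run_summary`: one row per segment with
#'   `tb_k`, `bt_k`, `tb_cl`, `bt_cl`, `net_events`, `dt_ns`, `ve_mv`,
#'   `current_pA`, `conductance_pS`.
#' @export
summarize_events <- function(events, dt_ns = NULL, ve_mv = NULL) {
  if (all(c("tb_k", "bt_k", "tb_cl", "bt_cl") %in% names(events))) {
    counts <- tibble::as_tibble(events)
    if (is.null(dt_ns) && "dt_ns" %in% names(counts)) dt_ns <- counts$dt_ns
    if (is.null(ve_mv) && "ve_mv" %in% names(counts)) ve_mv <- counts$ve_mv
  } else {
    if (is.null(dt_ns)) dt_ns <- attr(events, "dt_ns")
    if (is.null(ve_mv)) ve_mv <- attr(events, "ve_mv")
    counts <- events |>
      dplyr::group_by(.data$segment) |>
      dplyr::summarise(
        tb_k = sum(.data$direction == 1 & .data$species == "K+"),
        bt_k = sum(.data$direction == -1 & .data$species == "K+"),
        tb_cl = sum(.data$direction == 1 & .data$species == "Cl-"),
        bt_cl = sum(.data$direction == -1 & .data$species == "Cl-"),
        .groups = "drop")
  }
  if (is.null(dt_ns) || any(dt_ns <= 0)) abort("`dt_ns` must be positive.")
  if (is.null(ve_mv)) abort("`ve_mv` is required.")
  if (any(ve_mv == 0)) abort("Conductance undefined at Ve = 0 mV.")
  out <- counts |>
    dplyr::mutate(
      net_events = .data$tb_k + .data$bt_cl - .data$bt_k - .data$tb_cl,
      dt_ns = dt_ns, ve_mv = ve_mv,
      current_pA = .data$net_events * .E_CHARGE / (dt_ns * 1e-9) * 1e12,
      # magnitude convention: net TB cation flux at negative Ve gives positive G
      conductance_pS = abs(.data$current_pA) / abs(.data$ve_mv) * 1e3
    )
  class(out) <- c("run_summary", class(out))
  out
}

#' Aggregate per-segment summaries
#'
#' Column means with standard errors (sample sd over sqrt(n)),
#' sd-to-mean variability ratios per event class, and pooled totals.
#'
#' @param summaries a `run_summary` tibble with >= 2 rows.
#' @return a tibble with one row per column (`tb_k`, `bt_k`, `tb_cl`,
#'   `bt_cl`, `net_events`, `conductance_pS`) and columns `mean`, `se`,
#'   `sd`, `sd_over_mean`, `total`, `n`.
#' @export
aggregate_summaries <- function(summaries) {
  if (nrow(summaries) < 2) abort("Need at least 2 segment summaries.")
  if (dplyr::n_distinct(summaries$dt_ns) > 1) {
    abort("Mixed segment lengths: normalize explicitly before aggregating.")
  }
  cols <- c("tb_k", "bt_k", "tb_cl", "bt_cl", "net_events", "conductance_pS")
  purrr::map_dfr(cols, function(cl) {
    v <- summaries[[cl]]
    tibble::tibble(
      column = cl, mean = mean(v), sd = sd(v),
      se = sd(v) / sqrt(length(v)),
      sd_over_mean = if (mean(v) != 0) sd(v) / mean(v) else NA_real_,
      total = sum(v), n = length(v))
  })
}

#' Fit linear current-voltage relations per voltage branch
#'
#' Least-squares lines through the (Ve, I) points, fitted separately at
#' negative and positive potentials; the slope of each branch is the
#' single-channel conductance for that polarity (inward at negative
#' voltage, outward at positive).
#'
#' @param points tibble with columns `ve_mv` and `current_pA`.
#' @param through_origin force a zero intercept (default FALSE).
#' @param conf_level confidence level for the slope band (default 0.95).
#' @return an object of class `iv_fit`: per-branch slopes (pS), intercepts
#'   (pA) and confidence intervals. Branches with fewer than 2 points are
#'   omitted; a branch with a single distinct voltage is a singular fit and
#'   errors.
#' @export
fit_iv <- function(points, through_origin = FALSE, conf_level = 0.95) {
  stopifnot(all(c("ve_mv", "current_pA") %in% names(points)))
  branches <- list(negative = points[points$ve_mv < 0, ],
                   positive = points[points$ve_mv > 0, ])
  fits <- purrr::imap(branches, function(p, nm) {
    if (nrow(p) < 2) return(NULL)
    if (dplyr::n_distinct(p$ve_mv) < 2 && !through_origin) {
      abort(sprintf("Singular I-V fit: %s branch has one distinct voltage.", nm))
    }
    fm <- if (through_origin) lm(current_pA ~ 0 + ve_mv, data = p)
          else lm(current_pA ~ ve_mv, data = p)
    slope <- unname(coef(fm)[["ve_mv"]])
    ci <- tryCatch(
      suppressWarnings(suppressMessages(confint(fm, "ve_mv", level = conf_level))),
      error = function(e) matrix(c(NA, NA), 1))
    list(branch = nm, fit = fm,
         slope_pS = slope * 1e3,
         conf_low_pS = ci[1] * 1e3, conf_high_pS = ci[2] * 1e3,
         intercept_pA = if (through_origin) 0 else unname(coef(fm)[["(Intercept)"]]),
         sense = if (nm == "negative") "inward" else "outward",
         n = nrow(p))
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("No branch has >= 2 points.")
  structure(list(branches = fits, through_origin = through_origin),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  for (b in x$branches) {
    cat(sprintf("%s branch (%s): G = %.1f pS [%.1f, %.1f], n = %d\n",
                b$branch, b$sense, abs(b$slope_pS),
                abs(b$conf_low_pS), abs(b$conf_high_pS), b$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.iv_fit <- function(x, ...) {
  purrr::map_dfr(x$branches, function(b) {
    tibble::tibble(branch = b$branch, sense = b$sense,
                   slope_pS = b$slope_pS, intercept_pA = b$intercept_pA,
                   conf_low_pS = b$conf_low_pS, conf_high_pS = b$conf_high_pS,
                   n = b$n)
  })
}

#' @exportS3Method generics::glance
glance.iv_fit <- function(x, ...) {
  tibble::tibble(n_branches = length(x$branches),
                 through_origin = x$through_origin)
}
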