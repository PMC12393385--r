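#' Printed per-segment event counts at -102 mV
#'
#' The published summary of crossing events from ten independent runs of the
#' conducting open-state model at a membrane voltage of -102 mV, broken into
#' eighteen 200-ns segments. Columns are complete top-to-bottom (TB) and
#' bottom-to-top (BT) traversals per species; the net charge translocation
#' is `tb_k + bt_cl - bt_k - tb_cl`.
#'
#' @return tibble with columns `segment`, `tb_k`, `bt_k`, `tb_cl`, `bt_cl`,
#'   `dt_ns` (200) and `ve_mv` (-102), 18 rows.
#' @export
table1_counts <- function() {
  tibble::tribble(
    ~segment, ~tb_k, ~bt_k, ~tb_cl, ~bt_cl,
    "1",     50L, 17L, 0L, 0L,
    "2",     40L, 17L, 0L, 0L,
    "3",     32L, 20L, 0L, 0L,
    "4",     39L, 27L, 0L, 0L,
    "5",     31L, 21L, 0L, 0L,
    "6.a",   45L, 12L, 0L, 1L,
    "6.b",   45L, 16L, 0L, 0L,
    "7.a",   32L, 15L, 0L, 1L,
    "7.b",   28L,  6L, 0L, 0L,
    "8.a",   40L, 23L, 0L, 0L,
    "8.b",   62L, 16L, 0L, 0L,
    "9.a",   51L, 18L, 0L, 0L,
    "9.b",   43L, 13L, 0L, 1L,
    "10.a",  47L, 16L, 0L, 0L,
    "10.b",  39L, 10L, 0L, 1L,
    "10.c",  62L, 13L, 1L, 1L,
    "10.d",  65L, 14L, 0L, 0L,
    "10.e",  43L, 21L, 0L, 0L
  ) |>
    dplyr::mutate(dt_ns = 200, ve_mv = -102)
}
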